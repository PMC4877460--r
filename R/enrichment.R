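#' Gene-set collection with an explicit universe
#'
#' Over-representation p-values depend on the background universe, so it
#' must be supplied explicitly; sets must be non-empty subsets of it.
#'
#' @param sets Named list of character vectors (gene ids per set).
#' @param universe Character vector of all background gene ids.
#' @return An object of class `gene_set_collection`.
#' @export
gene_sets <- function(sets, universe) {
  if (!is.list(sets) || length(sets) == 0 || is.null(names(sets)) ||
      any(!nzchar(names(sets))))
    abort_arg("sets must be a non-empty named list")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) abort_arg("universe must be non-empty")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(vapply(sets, length, integer(1)) == 0))
    abort_arg("every gene set must be non-empty")
  stray <- setdiff(unique(unlist(sets)), universe)
  if (length(stray))
    abort_arg("gene sets contain ids outside the universe: ",
              paste(utils::head(stray, 5), collapse = ", "))
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the target list overlaps it more than
#' expected by chance: with universe size `N`, set size `K`, target size `n`
#' and overlap `k`, the one-sided p-value is `P(X >= k)` for
#' `X ~ Hypergeometric(N, K, n)` (Fisher's one-sided test). q-values are
#' Benjamini-Hochberg across the collection; rows are sorted by ascending
#' p-value.
#'
#' @param targets Character vector of target gene ids. Ids outside the
#'   universe are dropped with a warning.
#' @param collection A [gene_sets()] collection.
#' @return Data frame `set_id`, `k`, `K`, `n`, `N`, `p_value`, `q_value`.
#' @examples
#' gs <- gene_sets(list(s1 = c("g1", "g2")), universe = paste0("g", 1:20))
#' hypergeom_ora(c("g1", "g2", "g3"), gs)
#' @export
hypergeom_ora <- function(targets, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  targets <- unique(as.character(targets))
  if (length(targets) == 0) abort_arg("targets must be non-empty")
  outside <- setdiff(targets, collection$universe)
  if (length(outside)) {
    warning(length(outside), " target id(s) outside the universe dropped: ",
            paste(utils::head(outside, 5), collapse = ", "), call. = FALSE)
    targets <- setdiff(targets, outside)
  }
  if (length(targets) == 0)
    abort_arg("no targets remain inside the universe")
  N <- length(collection$universe)
  n <- length(targets)
  out <- do.call(rbind, lapply(names(collection$sets), function(id) {
    set <- collection$sets[[id]]
    K <- length(set)
    k <- length(intersect(targets, set))
    data.frame(set_id = id, k = k, K = K, n = n, N = N,
               p_value = phyper(k - 1, K, N - K, n, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  }))
  out$q_value <- bh_fdr(out$p_value)
  out <- out[order(out$p_value, out$set_id), ]
  rownames(out) <- NULL
  out
}

#' Read and write GMT gene-set files
#'
#' The standard tab-separated GMT layout: set id, description, then member
#' genes. Reading is delegated to [fgsea::gmtPathways()].
#'
#' @param path GMT file path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional per-set description column (defaults to the
#'   set ids).
#' @return `read_gmt()` returns a named list of character vectors.
#' @export
read_gmt <- function(path) {
  fgsea::gmtPathways(path)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = names(sets)) {
  if (is.null(names(sets))) abort_arg("sets must be named")
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Intersection of target-prediction lists
#'
#' Utility for the common workflow of intersecting the target-gene lists of
#' several prediction tools before enrichment.
#'
#' @param ... Two or more character vectors (or one list of them).
#' @return Character vector of genes present in every list.
#' @examples
#' intersect_target_lists(c("a", "b", "c"), c("b", "c"), c("c", "b", "d"))
#' @export
intersect_target_lists <- function(...) {
  lists <- list(...)
  if (length(lists) == 1 && is.list(lists[[1]])) lists <- lists[[1]]
  if (length(lists) < 2) abort_arg("need at least two lists to intersect")
  Reduce(intersect, lapply(lists, as.character))
}
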