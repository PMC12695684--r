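#' Ward hierarchical clustering of group trait profiles
#'
#' Agglomerative Ward minimum-variance clustering of (typically nine) group
#' mean trait profiles. Traits are z-scored across profiles first so that
#' heterogeneous units contribute comparably, then Euclidean distances feed
#' the Ward criterion in its squared-distance Lance-Williams form
#' (`hclust` method `ward.D2`), whose merge heights are non-decreasing.
#' Profiles are ordered by label before clustering, so the result is
#' invariant to input row order.
#'
#' @param profiles A tibble of profiles, one row per group.
#' @param labels Column holding the profile labels (default
#'   `"group_index"` if present, else row numbers).
#' @param traits Trait columns; defaults to all numeric non-label columns.
#' @param standardize z-score traits across profiles first (default TRUE).
#'   Constant traits are left at 0.
#'
#' @return An object of class `ward_cluster` wrapping the `hclust` tree;
#'   see [cut_tree()], [merge_table()], [as_newick()].
#' @export
ward_cluster <- function(profiles, labels = NULL, traits = NULL,
                         standardize = TRUE) {
  p <- tibble::as_tibble(profiles)
  if (is.null(labels)) {
    labels <- if ("group_index" %in% names(p)) "group_index" else NULL
  }
  lab <- if (is.null(labels)) as.character(seq_len(nrow(p))) else
    as.character(p[[labels]])
  if (anyDuplicated(lab)) stop("profile labels must be unique", call. = FALSE)
  if (is.null(traits)) {
    traits <- setdiff(names(p)[vapply(p, is.numeric, logical(1))], labels)
  }
  if (nrow(p) < 2) stop("domain error: need at least 2 profiles",
                        call. = FALSE)
  x <- as.matrix(p[, traits])
  rownames(x) <- lab
  x <- x[order(lab), , drop = FALSE]  # canonical order: row-order invariance
  if (standardize) {
    x <- apply(x, 2, function(col) {
      s <- stats::sd(col)
      if (s == 0) rep(0, length(col)) else (col - mean(col)) / s
    })
    rownames(x) <- sort(lab)
  }
  hc <- stats::hclust(stats::dist(x), method = "ward.D2")
  structure(list(hclust = hc, labels = hc$labels, traits = traits,
                 standardized = standardize),
            class = "ward_cluster")
}

#' @export
print.ward_cluster <- function(x, ...) {
  cat("<ward_cluster> ", length(x$labels), " profiles, ",
      length(x$traits), " traits (Ward.D2",
      if (x$standardized) ", z-scored" else "", ")\n", sep = "")
  print(merge_table(x))
  invisible(x)
}

#' Cut a Ward dendrogram into k clusters
#'
#' Removes the k - 1 highest merges, yielding k flat clusters with stable
#' labels.
#'
#' @param tree A [ward_cluster()] object.
#' @param k Number of clusters, between 1 and the number of leaves.
#'
#' @return A tibble with `label` and `cluster`.
#' @export
cut_tree <- function(tree, k) {
  stopifnot(inherits(tree, "ward_cluster"))
  n <- length(tree$labels)
  if (k < 1 || k > n) {
    stop("domain error: k must be in 1..", n, call. = FALSE)
  }
  cl <- stats::cutree(tree$hclust, k = k)
  tibble::tibble(label = names(cl), cluster = unname(cl))
}

#' Merge table of a Ward dendrogram
#'
#' @param tree A [ward_cluster()] object.
#'
#' @return A tibble with one row per merge: `node`, `child_1`, `child_2`
#'   (negative numbers are leaves, positive earlier merges, following
#'   `hclust` conventions) and `height`.
#' @export
merge_table <- function(tree) {
  stopifnot(inherits(tree, "ward_cluster"))
  hc <- tree$hclust
  tibble::tibble(
    node = seq_len(nrow(hc$merge)),
    child_1 = hc$merge[, 1],
    child_2 = hc$merge[, 2],
    height = hc$height
  )
}

#' Export a Ward dendrogram in Newick format
#'
#' @param tree A [ward_cluster()] object.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#'
#' @return The Newick string (invisibly when written to `path`).
#' @export
as_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "ward_cluster"))
  phy <- ape::as.phylo(tree$hclust)
  if (is.null(path)) {
    ape::write.tree(phy)
  } else {
    ape::write.tree(phy, file = path)
    invisible(ape::write.tree(phy))
  }
}
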