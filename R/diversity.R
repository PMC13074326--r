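#' Genetic distance between accessions from band codes
#'
#' Default metric is the simple-matching dissimilarity
#' `1 - matches / comparable`, where a marker is comparable when both
#' accessions have a non-missing (non-zero) code and a match when the
#' codes are identical. Missing data are handled by pairwise deletion. A
#' pair with no comparable marker gets `NA` with a warning.
#'
#' @param genotypes genotype tibble (see [read_genotypes()]).
#' @param metric currently `"simple_matching"`.
#' @return a `dist` object labelled with accession ids.
#' @export
genetic_distance <- function(genotypes, metric = "simple_matching") {
  metric <- match.arg(metric, "simple_matching")
  check_genotypes(genotypes)
  codes <- code_matrix(genotypes)
  codes[codes == 0L] <- NA_integer_
  n <- nrow(codes)
  if (n < 2L) abort("Need at least two accessions.")
  d <- matrix(0, n, n, dimnames = list(rownames(codes), rownames(codes)))
  for (i in seq_len(n - 1L)) {
    for (j in seq((i + 1L), n)) {
      both <- !is.na(codes[i, ]) & !is.na(codes[j, ])
      if (!any(both)) {
        warn(sprintf("Accessions %s and %s share no comparable markers.",
                     rownames(codes)[i], rownames(codes)[j]))
        d[i, j] <- d[j, i] <- NA_real_
      } else {
        d[i, j] <- d[j, i] <- 1 - mean(codes[i, both] == codes[j, both])
      }
    }
  }
  as.dist(d)
}

#' UPGMA tree from a distance matrix
#'
#' Average-linkage agglomeration; the returned tree is ultrametric with
#' branch lengths of half the merge heights, so cophenetic distances equal
#' the merge heights.
#'
#' @param d a complete `dist` object.
#' @return an [ape::as.phylo()] tree (`phylo`), with the underlying
#'   `hclust` object attached as attribute `"hclust"`.
#' @export
upgma_tree <- function(d) {
  if (anyNA(d)) abort("Distance matrix contains undefined entries.")
  hc <- hclust(as.dist(d), method = "average")
  tr <- ape::as.phylo(hc)
  attr(tr, "hclust") <- hc
  tr
}

#' Cut the UPGMA clustering into k groups
#'
#' @param d a complete `dist` object.
#' @param k number of groups.
#' @return named integer vector of group memberships.
#' @export
upgma_clusters <- function(d, k) {
  if (anyNA(d)) abort("Distance matrix contains undefined entries.")
  cutree(hclust(as.dist(d), method = "average"), k = k)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (via [ape::nj()]) followed by the standard
#' negative-branch correction: any negative branch length is set to zero
#' and its magnitude transferred to the adjacent sibling branch, which
#' preserves the path lengths between tips through the parent node.
#'
#' @param d a complete `dist` object with at least 3 taxa.
#' @return a `phylo` tree with non-negative branch lengths.
#' @export
nj_tree <- function(d) {
  if (anyNA(d)) abort("Distance matrix contains undefined entries.")
  if (attr(as.dist(d), "Size") < 3L) abort("Neighbor joining needs >= 3 taxa.")
  tr <- ape::nj(as.dist(d))
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amount <- -tr$edge.length[e]
    tr$edge.length[e] <- 0
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent)
    sibs <- setdiff(sibs, e)
    if (length(sibs)) {
      tr$edge.length[sibs[1]] <- tr$edge.length[sibs[1]] + amount
    }
  }
  tr
}

#' PCA of a band-code genotype matrix
#'
#' Codes are mapped to alternate-allele dosage (1 -> 0, 3 -> 1, 2 -> 2,
#' 4 -> 2; 0/missing imputed with the marker mean), columns are centred
#' (not scaled) and the accession covariance is eigendecomposed via
#' [stats::prcomp()]. Component signs are fixed by making each
#' component's largest-magnitude loading positive, so results are
#' reproducible across platforms.
#'
#' @param genotypes genotype tibble.
#' @param n_components number of components to keep (default
#'   `min(n - 1, markers, 10)`).
#' @return an `indel_pca` object: list with `coordinates` (tibble,
#'   `accession_id` + `PC*` columns) and `explained` (tibble of per-
#'   component explained variance fractions).
#' @export
pca_genotypes <- function(genotypes, n_components = NULL) {
  check_genotypes(genotypes)
  if (nrow(genotypes) < 2L) abort("Need at least two accessions.")
  d <- impute_col_mean(dosage_matrix(genotypes))
  p <- prcomp(d, center = TRUE, scale. = FALSE)
  total_var <- sum(p$sdev^2)
  k <- n_components %||% min(nrow(d) - 1L, ncol(d), 10L)
  k <- min(k, ncol(p$x))
  # fix signs: largest-magnitude loading positive
  for (j in seq_len(k)) {
    lead <- which.max(abs(p$rotation[, j]))
    if (p$rotation[lead, j] < 0) {
      p$rotation[, j] <- -p$rotation[, j]
      p$x[, j] <- -p$x[, j]
    }
  }
  coords <- as_tibble(p$x[, seq_len(k), drop = FALSE])
  coords <- bind_cols(tibble(accession_id = genotypes$accession_id), coords)
  explained <- if (total_var > 0) p$sdev[seq_len(k)]^2 / total_var else
    rep(0, k)
  structure(list(coordinates = coords,
                 explained = tibble(component = paste0("PC", seq_len(k)),
                                    explained_variance = explained)),
            class = "indel_pca")
}

#' @export
print.indel_pca <- function(x, ...) {
  cat(sprintf("PCA of %d accessions, %d components\n",
              nrow(x$coordinates), nrow(x$explained)))
  print(x$explained, ...)
  invisible(x)
}

#' @describeIn pca_genotypes tidy(): accession coordinates in long format.
#' @param x an `indel_pca` object.
#' @param ... unused.
#' @export
tidy.indel_pca <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"accession_id",
                      names_to = "component", values_to = "coordinate")
}

#' @describeIn pca_genotypes glance(): explained variance fractions, wide.
#' @export
glance.indel_pca <- function(x, ...) {
  tidyr::pivot_wider(x$explained, names_from = "component",
                     values_from = "explained_variance")
}

#' @describeIn pca_genotypes autoplot(): PC1/PC2 scatter, optionally
#'   coloured by a named group vector.
#' @param object an `indel_pca` object.
#' @param groups optional named vector (names = accession ids) used to
#'   colour points.
#' @export
autoplot.indel_pca <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("%s (%.1f%%)", object$explained$component[i],
                             100 * object$explained$explained_variance[i])
  df$group <- if (is.null(groups)) "all" else
    as.factor(groups[df$accession_id])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2,
                                   colour = .data$group)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2), colour = NULL) +
    ggplot2::theme_minimal()
}
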