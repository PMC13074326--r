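# Simplified admixture model: each accession i draws each of its two
# allele copies at marker j from ancestral cluster k with probability
# q_ik, and the copy is the alternate allele with probability p_kj. The
# alternate-dosage g_ij is then Binomial(2, f_ij) with f = Q P. Q and P
# are estimated by maximum likelihood via EM; the fitted log-likelihood
# serves as the lnP(K) analogue for model selection.

# run code with a temporary RNG state seeded by `seed`
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

EPS <- 1e-9

admixture_loglik <- function(G, Q, P) {
  f <- Q %*% P
  f <- pmin(pmax(f, EPS), 1 - EPS)
  sum(dbinom(G, 2, f, log = TRUE), na.rm = TRUE)
}

#' Fit the admixture model by EM
#'
#' Maximum-likelihood estimation of membership fractions `Q` (accessions x
#' K) and cluster allele frequencies `P` (K x markers) under the binomial
#' admixture likelihood, by expectation-maximisation from a seeded random
#' start. Missing genotypes contribute nothing to either step. `K = 1` is
#' handled in closed form (`Q` a column of ones, `P` the observed
#' frequencies). The EM log-likelihood sequence is non-decreasing.
#'
#' @param genotypes genotype tibble; band codes are collapsed to biallelic
#'   alternate dosage (1 -> 0, 3 -> 1, 2 and 4 -> 2, 0 -> missing).
#' @param K number of ancestral clusters (`1 <= K <=` accessions).
#' @param seed integer seed for the random initialisation.
#' @param max_iter maximum EM iterations.
#' @param tol stop when the log-likelihood improves by less than this.
#' @return an `admixture_fit`: list with `K`, `Q`, `P`, `loglik`,
#'   `loglik_trace`, `n_iter`, `seed`, `converged`, `accession_ids`.
#' @export
fit_admixture_em <- function(genotypes, K, seed = 1, max_iter = 500,
                             tol = 1e-6) {
  check_genotypes(genotypes)
  G <- dosage_matrix(genotypes)
  n <- nrow(G); M <- ncol(G)
  if (K < 1 || K > n) abort("K must be between 1 and the number of accessions.")
  obs <- !is.na(G)
  if (K == 1) {
    P <- matrix(colMeans(G, na.rm = TRUE) / 2, 1, M)
    P[is.nan(P)] <- 0.5
    Q <- matrix(1, n, 1)
    ll <- admixture_loglik(G, Q, P)
    return(structure(list(K = 1L, Q = Q, P = P, loglik = ll,
                          loglik_trace = ll, n_iter = 0L, seed = seed,
                          converged = TRUE,
                          accession_ids = genotypes$accession_id),
                     class = "admixture_fit"))
  }
  init <- with_seed(seed, {
    Q0 <- matrix(stats::rexp(n * K), n, K)
    list(Q = Q0 / rowSums(Q0), P = matrix(runif(K * M, 0.05, 0.95), K, M))
  })
  Q <- init$Q; P <- init$P
  G0 <- G; G0[!obs] <- 0  # contributions zeroed at missing cells
  M_i <- rowSums(obs)
  trace <- admixture_loglik(G, Q, P)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    f <- pmin(pmax(Q %*% P, EPS), 1 - EPS)
    Anum <- G0 / f            # n x M, scaled per-cluster below
    Bnum <- (2 - G0) / (1 - f)
    Anum[!obs] <- 0; Bnum[!obs] <- 0
    Qnew <- matrix(0, n, K); Pnew <- matrix(0, K, M)
    for (k in seq_len(K)) {
      share_a <- Anum * (Q[, k] %o% P[k, ])        # expected alt copies from k
      share_b <- Bnum * (Q[, k] %o% (1 - P[k, ]))  # expected ref copies from k
      Qnew[, k] <- rowSums(share_a + share_b) / (2 * M_i)
      tot <- colSums(share_a + share_b)
      Pnew[k, ] <- ifelse(tot > 0, colSums(share_a) / tot, P[k, ])
    }
    Q <- Qnew / rowSums(Qnew)  # guard rounding; rows are simplex-valid
    P <- pmin(pmax(Pnew, 0), 1)
    ll <- admixture_loglik(G, Q, P)
    improve <- ll - tail(trace, 1)
    trace <- c(trace, ll)
    if (abs(improve) < tol) { converged <- TRUE; break }
  }
  structure(list(K = as.integer(K), Q = Q, P = P, loglik = tail(trace, 1),
                 loglik_trace = trace, n_iter = length(trace) - 1L,
                 seed = seed, converged = converged,
                 accession_ids = genotypes$accession_id),
            class = "admixture_fit")
}

#' @export
print.admixture_fit <- function(x, ...) {
  cat(sprintf("Admixture fit: K = %d, %d accessions, log-likelihood %.3f (%d EM iterations%s)\n",
              x$K, nrow(x$Q), x$loglik, x$n_iter,
              if (x$converged) ", converged" else ""))
  invisible(x)
}

#' @describeIn fit_admixture_em tidy(): long tibble of membership
#'   fractions (`accession_id`, `cluster`, `proportion`).
#' @param x an `admixture_fit`.
#' @param ... unused.
#' @export
tidy.admixture_fit <- function(x, ...) {
  q <- as_tibble(x$Q, .name_repair = ~ paste0("K", seq_along(.x)))
  q$accession_id <- x$accession_ids
  tidyr::pivot_longer(q, -"accession_id", names_to = "cluster",
                      values_to = "proportion")
}

#' @describeIn fit_admixture_em glance(): one-row fit summary.
#' @export
glance.admixture_fit <- function(x, ...) {
  tibble(K = x$K, loglik = x$loglik, n_iter = x$n_iter,
         converged = x$converged, seed = x$seed)
}

#' @describeIn fit_admixture_em autoplot(): stacked membership bars per
#'   accession.
#' @param object an `admixture_fit`.
#' @export
autoplot.admixture_fit <- function(object, ...) {
  df <- tidy(object)
  df$accession_id <- factor(df$accession_id, levels = object$accession_ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$accession_id,
                                   y = .data$proportion,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Membership", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Replicated admixture fits over a range of K
#'
#' Fits the admixture model `n_rep` times per K value (distinct derived
#' seeds per replicate), mirroring the practice of running the clustering
#' program several times per K before model selection.
#'
#' @inheritParams fit_admixture_em
#' @param K_range integer vector of K values (default 1:10).
#' @param n_rep replicates per K (default 10).
#' @return tibble of class `admixture_scan`: `K`, `rep`, `seed`, `loglik`
#'   and the fit itself in a list column.
#' @export
admixture_scan <- function(genotypes, K_range = 1:10, n_rep = 10, seed = 1,
                           max_iter = 500, tol = 1e-6) {
  grid <- tidyr::expand_grid(K = sort(unique(K_range)), rep = seq_len(n_rep))
  grid$seed <- (seed * 1000L + grid$K * 100L + grid$rep) %% .Machine$integer.max
  fits <- purrr::pmap(grid, function(K, rep, seed) {
    fit_admixture_em(genotypes, K, seed = seed, max_iter = max_iter, tol = tol)
  })
  grid$loglik <- vapply(fits, `[[`, numeric(1), "loglik")
  grid$fit <- fits
  class(grid) <- c("admixture_scan", class(grid))
  grid
}

#' Cross-validation error for an admixture model
#'
#' Masks a random fold of the observed genotype cells, fits the model on
#' the remainder and scores the mean squared difference between the
#' predicted dosage expectation `2 Q P` and the held-out dosages;
#' averaged over folds. Markers left with no training observations in a
#' fold are skipped for that fold (reported).
#'
#' @inheritParams fit_admixture_em
#' @param n_folds number of folds (>= 2, default 5).
#' @return mean held-out squared error (non-negative scalar).
#' @export
cv_error <- function(genotypes, K, n_folds = 5, seed = 1, max_iter = 500,
                     tol = 1e-6) {
  check_genotypes(genotypes)
  if (n_folds < 2) abort("n_folds must be >= 2.")
  G <- dosage_matrix(genotypes)
  cells <- which(!is.na(G))
  folds <- with_seed(seed, sample(rep(seq_len(n_folds), length.out =
                                        length(cells))))
  errs <- vapply(seq_len(n_folds), function(f) {
    held <- cells[folds == f]
    Gtrain <- G
    Gtrain[held] <- NA
    empty <- which(colSums(!is.na(Gtrain)) == 0)
    if (length(empty)) {
      inform(sprintf("Fold %d: %d marker(s) with no training observations skipped.",
                     f, length(empty)))
      held_col <- ((held - 1L) %/% nrow(G)) + 1L
      held <- held[!held_col %in% empty]
      Gtrain[, empty] <- NA
    }
    fit <- fit_admixture_from_dosage(Gtrain, genotypes$accession_id, K,
                                     seed = seed + f, max_iter = max_iter,
                                     tol = tol)
    pred <- 2 * fit$Q %*% fit$P
    mean((pred[held] - G[held])^2)
  }, numeric(1))
  mean(errs)
}

# internal: fit directly from a dosage matrix (used by cv_error, where the
# training data are a masked dosage matrix rather than band codes)
fit_admixture_from_dosage <- function(G, ids, K, seed, max_iter, tol) {
  # re-render dosage as band codes so the public fitter can be reused
  codes <- matrix(0L, nrow(G), ncol(G))
  codes[!is.na(G) & G == 0] <- 1L
  codes[!is.na(G) & G == 1] <- 3L
  codes[!is.na(G) & G == 2] <- 2L
  g <- as_tibble(as.data.frame(codes), .name_repair = ~ paste0("m", seq_along(.x)))
  g <- bind_cols(tibble(accession_id = ids), g)
  fit_admixture_em(g, K, seed = seed, max_iter = max_iter, tol = tol)
}

#' Evanno delta-K model-selection table
#'
#' From replicate log-likelihoods per K, computes the mean and standard
#' deviation of `lnP(K)` and the Evanno statistic: the mean over
#' replicates of the absolute second difference
#' `|L(K+1) - 2 L(K) + L(K-1)|`, divided by the replicate standard
#' deviation at K. Delta-K is undefined at the boundary K values and
#' infinite when the replicate standard deviation is zero.
#'
#' The statistic was designed for Monte-Carlo samplers whose replicate
#' runs scatter; an EM fitter run to convergence produces replicate
#' spreads bounded only by the stopping tolerance at small K, which makes
#' the raw ratio blow up wherever the curvature is non-zero. `sd_floor`
#' bounds the normalising standard deviation from below (in log-likelihood
#' units); with the default 0 the statistic is the classical one, while
#' [selection_table()] uses a floor of 1 so that numerically identical
#' replicates fall back to the raw curvature `|L''(K)|`.
#'
#' @param replicates data frame with columns `K` and `loglik` (one row per
#'   replicate run), e.g. an [admixture_scan()].
#' @param sd_floor lower bound for the normalising standard deviation, in
#'   log-likelihood units (default 0 = classical Evanno).
#' @return tibble with `K`, `n_rep`, `mean_lnpk`, `sd_lnpk`, `delta_k`.
#' @export
evanno_delta_k <- function(replicates, sd_floor = 0) {
  if (!all(c("K", "loglik") %in% names(replicates))) {
    abort("`replicates` needs columns K and loglik.")
  }
  ks <- sort(unique(replicates$K))
  if (length(ks) < 3) abort("Need at least 3 consecutive K values.")
  byk <- lapply(ks, function(k) sort(replicates$loglik[replicates$K == k]))
  n_rep <- lengths(byk)
  if (any(n_rep < 2)) abort("Need at least 2 replicates per K.")
  means <- vapply(byk, mean, numeric(1))
  sds <- vapply(byk, sd, numeric(1))
  delta <- rep(NA_real_, length(ks))
  for (i in seq_along(ks)[-c(1, length(ks))]) {
    if (ks[i + 1] - ks[i] != 1 || ks[i] - ks[i - 1] != 1) next
    if (length(unique(n_rep[(i - 1):(i + 1)])) == 1L) {
      second <- byk[[i + 1]] - 2 * byk[[i]] + byk[[i - 1]]
      num <- mean(abs(second))
    } else {
      num <- abs(means[i + 1] - 2 * means[i] + means[i - 1])
    }
    denom <- max(sds[i], sd_floor)
    delta[i] <- if (denom == 0) Inf else num / denom
  }
  tibble(K = ks, n_rep = n_rep, mean_lnpk = means, sd_lnpk = sds,
         delta_k = delta)
}

#' Model-selection summary across K
#'
#' Joins the Evanno table from a replicate scan with per-K
#' cross-validation errors, the two selection statistics reported side by
#' side.
#'
#' @param scan an [admixture_scan()] result.
#' @param genotypes genotype tibble (for the CV errors); `NULL` skips CV.
#' @param n_folds,seed CV parameters, see [cv_error()].
#' @param sd_floor passed to [evanno_delta_k()]; default 1 log-likelihood
#'   unit (see its help for why EM replicates need a floor).
#' @return tibble with `K`, `mean_lnpk`, `sd_lnpk`, `delta_k`,
#'   `cv_error`, plus attributes `k_delta` (arg max delta-K) and `k_cv`
#'   (arg min CV error).
#' @export
selection_table <- function(scan, genotypes = NULL, n_folds = 5, seed = 1,
                            sd_floor = 1) {
  tab <- evanno_delta_k(scan, sd_floor = sd_floor)
  if (!is.null(genotypes)) {
    tab$cv_error <- vapply(tab$K, function(k) {
      cv_error(genotypes, k, n_folds = n_folds, seed = seed)
    }, numeric(1))
    attr(tab, "k_cv") <- tab$K[which.min(tab$cv_error)]
  }
  finite <- which(is.finite(tab$delta_k))
  if (length(finite)) attr(tab, "k_delta") <- tab$K[finite[which.max(tab$delta_k[finite])]]
  tab
}

#' Greedy alignment of cluster labels between two fits
#'
#' Cluster labels are arbitrary across replicate fits; for plotting,
#' matches columns of `fit$Q` to `reference$Q` greedily by highest
#' column correlation. Alignment only relabels columns.
#'
#' @param fit,reference `admixture_fit` objects with equal K.
#' @return `fit` with `Q` (and `P`) columns permuted to match `reference`.
#' @export
align_clusters <- function(fit, reference) {
  if (fit$K != reference$K) abort("Fits must share K.")
  K <- fit$K
  if (K == 1L) return(fit)
  cors <- suppressWarnings(stats::cor(reference$Q, fit$Q))
  cors[is.na(cors)] <- 0
  perm <- integer(K)
  for (step in seq_len(K)) {
    idx <- arrayInd(which.max(cors), dim(cors))
    perm[idx[1]] <- idx[2]
    cors[idx[1], ] <- -Inf
    cors[, idx[2]] <- -Inf
  }
  fit$Q <- fit$Q[, perm, drop = FALSE]
  fit$P <- fit$P[perm, , drop = FALSE]
  fit
}

#' Write a Q matrix as TSV
#'
#' @param fit an `admixture_fit`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_q_matrix <- function(fit, path) {
  q <- as_tibble(fit$Q, .name_repair = ~ paste0("K", seq_along(.x)))
  readr::write_tsv(bind_cols(tibble(accession_id = fit$accession_ids), q),
                   path, progress = FALSE)
  invisible(path)
}
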