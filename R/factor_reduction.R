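# Latent factor reduction of the 48-feature matrix: parallel analysis for
# the factor count, maximum-likelihood factor analysis on the correlation
# matrix with oblimin rotation, chi-square goodness of fit, tenBerge
# (correlation-preserving) factor scores, and primary-component
# identification at |loading| > 0.3.

ID_COLS <- c("subject_id", "group", "stage", "sentence")

feature_columns <- function(data) {
  nm <- setdiff(colnames(data), ID_COLS)
  nm[vapply(data[nm], is.numeric, logical(1))]
}

feature_matrix <- function(data, na_action = c("impute", "drop")) {
  na_action <- match.arg(na_action)
  x <- as.matrix(data[feature_columns(data)])
  if (anyNA(x)) {
    if (na_action == "drop") {
      keep <- complete.cases(x)
      inform(sprintf("dropped %d incomplete records.", sum(!keep)))
      x <- x[keep, , drop = FALSE]
    } else {
      n_imp <- sum(is.na(x))
      for (j in seq_len(ncol(x))) {
        nas <- is.na(x[, j])
        if (any(nas)) x[nas, j] <- median(x[, j], na.rm = TRUE)
      }
      inform(sprintf("imputed %d missing cells with column medians.", n_imp))
    }
  }
  cv <- apply(x, 2, var)
  if (any(cv <= 0)) {
    abort(paste0("constant feature column(s) after screening: ",
                 paste(colnames(x)[cv <= 0], collapse = ", ")))
  }
  x
}

#' Parallel analysis for the number of latent factors
#'
#' Compares the eigenvalues of the observed correlation matrix with the
#' 95th percentile (by default) of eigenvalues from `n_sim` random
#' standard-normal datasets of identical shape. The retained count is the
#' number of leading observed eigenvalues exceeding their simulated
#' quantile.
#'
#' @param data Tibble or matrix of feature records (id columns ignored).
#' @param n_sim Number of simulated datasets (default 100).
#' @param quantile Simulation quantile (default 0.95).
#' @param seed Seed for the simulated eigenvalue draws.
#' @param na_action Handling of missing cells: `"impute"` (column median)
#'   or `"drop"` rows.
#' @return An object of class `parallel_analysis`: list with `n_factors`,
#'   `eigenvalues`, `thresholds`.
#' @export
parallel_analysis <- function(data, n_sim = 100L, quantile = 0.95,
                              seed = NULL, na_action = "impute") {
  x <- feature_matrix(data, na_action)
  n <- nrow(x); p <- ncol(x)
  if (n < 3L) abort("parallel analysis needs at least 3 records.")
  if (n <= p) warn("fewer records than features; retained counts are unstable.")
  obs <- eigen(cor(x), symmetric = TRUE, only.values = TRUE)$values
  sims <- with_seed(seed, {
    vapply(seq_len(n_sim), function(s) {
      eigen(cor(matrix(rnorm(n * p), n, p)), symmetric = TRUE,
            only.values = TRUE)$values
    }, numeric(p))
  })
  thr <- apply(sims, 1L, stats::quantile, probs = quantile)
  exceeds <- obs > thr
  k <- if (exceeds[1]) which.min(c(exceeds, FALSE)) - 1L else 0L
  structure(list(n_factors = as.integer(k), eigenvalues = obs, thresholds = thr,
                 n_sim = n_sim, quantile = quantile),
            class = "parallel_analysis")
}

#' @export
print.parallel_analysis <- function(x, ...) {
  cat(sprintf("<parallel_analysis> %d factor(s) retained (%d sims, %.0f%% quantile)\n",
              x$n_factors, x$n_sim, 100 * x$quantile))
  invisible(x)
}

# Quartimin criterion value and gradient (oblimin with gamma = 0).
quartimin_vg <- function(L) {
  L2 <- L^2
  k <- ncol(L)
  N <- matrix(1, k, k) - diag(k)
  X <- L2 %*% N
  list(f = sum(L2 * X) / 4, Gq = L * X)
}

# Oblique gradient-projection rotation (quartimin criterion).
rotate_oblimin <- function(A, maxit = 1000L, eps = 1e-6) {
  k <- ncol(A)
  if (k == 1L) return(list(loadings = A, Phi = matrix(1, 1, 1)))
  Tm <- diag(k)
  al <- 1
  Ti <- solve(Tm)
  L <- A %*% t(Ti)
  vg <- quartimin_vg(L)
  f <- vg$f
  G <- -t(t(L) %*% vg$Gq %*% Ti)
  for (iter in seq_len(maxit)) {
    Gp <- G - Tm %*% diag(colSums(Tm * G))
    s <- sqrt(sum(Gp^2))
    if (s < eps) break
    al <- 2 * al
    for (i in 0:25) {
      X <- Tm - al * Gp
      v <- 1 / sqrt(colSums(X^2))
      Tt <- X %*% diag(v)
      Tit <- solve(Tt)
      Lt <- A %*% t(Tit)
      vgt <- quartimin_vg(Lt)
      if (vgt$f < f - 0.5 * s^2 * al) break
      al <- al / 2
    }
    Tm <- Tt; Ti <- Tit; L <- Lt; f <- vgt$f
    G <- -t(t(L) %*% vgt$Gq %*% Ti)
  }
  list(loadings = L, Phi = t(Tm) %*% Tm)
}

#' Fit the maximum-likelihood factor model
#'
#' ML factor analysis on the correlation matrix of the (standardized)
#' features, followed by oblimin (quartimin, gamma = 0) rotation. Factors
#' are ordered by explained variance and sign-aligned so each factor's
#' largest loading is positive. Reports the chi-square goodness-of-fit
#' statistic and the cumulative variance (sum of squared structure
#' loadings over the number of features). A non-positive-definite
#' correlation matrix is ridge-regularized with a message; Heywood cases
#' (uniquenesses at the boundary) are reported with a warning, not
#' silently clipped.
#'
#' @param data Tibble of feature records (id columns ignored).
#' @param n_factors Number of factors; `NULL` runs [parallel_analysis()].
#' @param seed Seed (used only when `n_factors` is `NULL`).
#' @param rotate `"oblimin"` (default) or `"none"`.
#' @param na_action Missing-cell handling, see [parallel_analysis()].
#' @return An object of class `muscle_factor_model`.
#' @export
fit_factor_model <- function(data, n_factors = NULL, seed = NULL,
                             rotate = c("oblimin", "none"),
                             na_action = "impute") {
  rotate <- match.arg(rotate)
  x <- feature_matrix(data, na_action)
  n <- nrow(x); p <- ncol(x)
  if (is.null(n_factors)) {
    pa <- parallel_analysis(data, seed = seed, na_action = na_action)
    n_factors <- pa$n_factors
    if (n_factors < 1L) abort("parallel analysis retained no factors; supply `n_factors`.")
  }
  k <- as.integer(n_factors)
  if (k < 1L) abort("`n_factors` must be at least 1.")
  df <- ((p - k)^2 - (p + k)) / 2
  if (df <= 0) abort(sprintf("%d factors leave no degrees of freedom for %d features.", k, p))
  R <- cor(x)
  ridge <- 0
  while (inherits(try(chol(R), silent = TRUE), "try-error")) {
    ridge <- if (ridge == 0) 1e-8 else ridge * 10
    if (ridge > 1e-2) abort("correlation matrix is irreparably non-positive-definite.")
    R <- (1 - ridge) * cor(x) + ridge * diag(p)
  }
  if (ridge > 0) inform(sprintf("correlation matrix ridge-regularized (ridge = %g).", ridge))
  fa <- factanal(covmat = R, factors = k, n.obs = n, rotation = "none")
  if (any(fa$uniquenesses <= 0.005 + 1e-9)) {
    warn(paste0("Heywood case: uniqueness at the boundary for ",
                paste(names(fa$uniquenesses)[fa$uniquenesses <= 0.005 + 1e-9],
                      collapse = ", ")))
  }
  A <- unclass(fa$loadings)
  if (rotate == "oblimin" && k > 1L) {
    rot <- rotate_oblimin(A)
    lambda <- rot$loadings
    phi <- rot$Phi
  } else {
    lambda <- A
    phi <- diag(k)
  }
  # order by explained variance, align signs
  ssq <- colSums((lambda %*% phi)^2)
  ord <- order(ssq, decreasing = TRUE)
  lambda <- lambda[, ord, drop = FALSE]
  phi <- phi[ord, ord, drop = FALSE]
  flip <- vapply(seq_len(k), function(j) {
    sign(lambda[which.max(abs(lambda[, j])), j])
  }, numeric(1))
  lambda <- sweep(lambda, 2L, flip, `*`)
  phi <- diag(flip) %*% phi %*% diag(flip)
  dimnames(lambda) <- list(colnames(x), paste0("factor", seq_len(k)))
  dimnames(phi) <- list(colnames(lambda), colnames(lambda))
  struct_load <- lambda %*% phi
  structure(
    list(loadings = lambda, Phi = phi, uniquenesses = fa$uniquenesses,
         n_factors = k,
         fit = list(chisq = unname(fa$STATISTIC), df = unname(fa$dof),
                    p.value = unname(fa$PVAL)),
         cumulative_variance = sum(struct_load^2) / p,
         correlation = R,
         center = colMeans(x), scale = apply(x, 2, sd),
         feature_names = colnames(x), n_obs = n,
         data = x),
    class = "muscle_factor_model"
  )
}

#' @export
print.muscle_factor_model <- function(x, ...) {
  cat(sprintf(
    "<muscle_factor_model> %d features, %d factors\n  chi-square(%d) = %.2f, p = %.3g; cumulative variance %.1f%%\n",
    length(x$feature_names), x$n_factors, x$fit$df, x$fit$chisq,
    x$fit$p.value, 100 * x$cumulative_variance
  ))
  invisible(x)
}

# tenBerge correlation-preserving score weights:
# W = R^{-1/2} C (C'C)^{-1/2} Phi^{1/2}, C = R^{-1/2} Lambda Phi^{1/2};
# then cor(Z W) = Phi exactly.
ten_berge_weights <- function(R, lambda, phi) {
  phi_s <- mat_sqrt(phi)
  r_is <- mat_sqrt(R, inverse = TRUE)
  C <- r_is %*% lambda %*% phi_s
  ctc <- t(C) %*% C
  if (min(eigen(ctc, symmetric = TRUE, only.values = TRUE)$values) < 1e-10) {
    abort("singular loading structure; tenBerge scores are undefined.")
  }
  r_is %*% C %*% mat_sqrt(ctc, inverse = TRUE) %*% phi_s
}

#' tenBerge factor scores
#'
#' Correlation-preserving factor score estimates: on the fitting sample
#' the scores have mean 0, SD 1 and inter-score correlations equal to the
#' model's inter-factor correlations.
#'
#' @param model A `muscle_factor_model`.
#' @param data Optional new records (defaults to the fitting sample); id
#'   columns, if present, are carried through.
#' @return Tibble of factor score columns (`factor1`, ...), preceded by
#'   any id columns.
#' @export
factor_scores <- function(model, data = NULL) {
  stopifnot(inherits(model, "muscle_factor_model"))
  ids <- NULL
  if (is.null(data)) {
    x <- model$data
  } else {
    idc <- intersect(ID_COLS, colnames(data))
    if (length(idc)) ids <- data[idc]
    x <- as.matrix(data[model$feature_names])
  }
  z <- sweep(sweep(x, 2L, model$center), 2L, model$scale, `/`)
  w <- ten_berge_weights(model$correlation, model$loadings, model$Phi)
  s <- z %*% w
  colnames(s) <- colnames(model$loadings)
  out <- tibble::as_tibble(s)
  if (!is.null(ids)) out <- dplyr::bind_cols(ids, out)
  out
}

#' Primary component features of each factor
#'
#' Features whose absolute rotated loading exceeds the threshold
#' (convention: 0.3), per factor, in descending absolute loading order.
#'
#' @param model A `muscle_factor_model`.
#' @param threshold Absolute loading threshold (default 0.3).
#' @return Tibble with columns `factor`, `feature`, `loading`.
#' @export
primary_components <- function(model, threshold = 0.3) {
  stopifnot(inherits(model, "muscle_factor_model"))
  out <- tibble::as_tibble(as.table(model$loadings), .name_repair = "minimal")
  names(out) <- c("feature", "factor", "loading")
  out <- dplyr::filter(out, abs(.data$loading) > threshold)
  out <- dplyr::arrange(out, .data$factor, dplyr::desc(abs(.data$loading)))
  empty <- setdiff(colnames(model$loadings), unique(out$factor))
  if (length(empty)) {
    warn(paste0("no feature loads above the threshold on: ",
                paste(empty, collapse = ", ")))
  }
  dplyr::select(out, "factor", "feature", "loading")
}
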