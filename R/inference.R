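# Disease-effect inference: linear mixed-effects models with estimated
# marginal mean contrasts, backward-stepwise LME linking factor scores to
# jaw kinematics, and repeated cross-validated classification.

# Nakagawa-Schielzeth variance-partition R-squared for an lmer fit.
r2_nakagawa <- function(model) {
  fe <- lme4::fixef(model)
  X <- lme4::getME(model, "X")
  var_f <- var(as.vector(X %*% fe))
  vc <- lme4::VarCorr(model)
  var_r <- sum(vapply(vc, function(v) sum(diag(v)), numeric(1)))
  var_e <- attr(vc, "sc")^2
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}

fit_lme_feature <- function(data, feature, within, levels_within) {
  cols <- paste0(feature, "_", levels_within)
  missing_cols <- setdiff(cols, colnames(data))
  if (length(missing_cols)) {
    abort(paste0("feature columns not found: ", paste(missing_cols, collapse = ", ")))
  }
  long <- tidyr::pivot_longer(
    data[c("subject_id", "group", cols)],
    cols = dplyr::all_of(cols),
    names_to = within, names_prefix = paste0(feature, "_"),
    values_to = "value"
  )
  long <- dplyr::filter(long, is.finite(.data$value))
  long$group <- factor(long$group)
  long[[within]] <- factor(long[[within]], levels = levels_within)
  if (nlevels(long$group) < 2L) abort("both groups must be present.")
  if (var(long$value) <= 0) abort(sprintf("feature '%s' has zero variance.", feature))
  n_per <- table(unique(long[c("subject_id", "group")])$group)
  if (any(n_per < 2L)) abort("need at least 2 subjects per group.")
  fml <- as.formula(paste0("value ~ group * ", within, " + (1 | subject_id)"))
  ctr <- setNames(list("contr.sum", "contr.sum"), c("group", within))
  m <- lmerTest::lmer(fml, data = long, contrasts = ctr)
  if (lme4::isSingular(m)) {
    warn(paste0("singular mixed-model fit for '", feature,
                "' (a random-effect variance is zero)."))
  }
  an <- as.data.frame(anova(m, type = 3))
  an_tb <- tibble::tibble(
    effect = rownames(an),
    statistic = an[["F value"]],
    df1 = an[["NumDF"]], df2 = an[["DenDF"]],
    p.value = an[["Pr(>F)"]]
  )
  emm <- emmeans::emmeans(m, as.formula(paste0("~ group | ", within)),
                          lmer.df = "satterthwaite")
  ct <- summary(emmeans::contrast(emm, method = "revpairwise"))
  k <- length(levels_within)
  contrasts <- tibble::tibble(
    level = as.character(ct[[within]]),
    estimate = ct$estimate,
    statistic = ct$t.ratio,
    p.value = ct$p.value,
    adj.p.value = pmin(1, ct$p.value * k)
  )
  structure(
    list(model = m, feature = feature, within = within,
         anova = an_tb, contrasts = contrasts, r2 = r2_nakagawa(m)),
    class = "muscle_lme"
  )
}

#' Mixed-effects disease model for a nodal feature family
#'
#' Fits `value ~ group * node + (1 | subject)` across the six muscles for
#' a nodal feature family (`"density"` or `"specradRatio"`), with
#' Satterthwaite F tests and estimated-marginal-mean ALS-vs-control
#' contrasts per node, Bonferroni-adjusted over the 6 nodes.
#'
#' @param data Feature table with `subject_id`, `group` and the
#'   `<feature>_<CH>` columns.
#' @param feature `"density"` or `"specradRatio"` (any prefix with
#'   per-channel columns works).
#' @return An object of class `muscle_lme` with `anova`, `contrasts` and
#'   Nakagawa marginal/conditional `r2`.
#' @export
fit_lme_nodal <- function(data, feature = "density") {
  fit_lme_feature(data, feature, "node", MN_CHANNELS)
}

#' Mixed-effects disease model for an edgewise feature family
#'
#' Fits `value ~ group * band + (1 | subject)` across the three frequency
#' bands for an edgewise feature family (e.g. `"nodstr"`, `"ge"`, `"ac"`,
#' `"wcc_RTEMP"`, `"lat_MAS_ABD"`), with contrasts per band,
#' Bonferroni-adjusted over the 3 bands.
#'
#' @param data Feature table with `subject_id`, `group` and
#'   `<feature>_<band>` columns.
#' @param feature Edgewise feature family prefix.
#' @return A `muscle_lme` object.
#' @export
fit_lme_edgewise <- function(data, feature = "nodstr") {
  fit_lme_feature(data, feature, "band", names(MN_BANDS))
}

#' @export
print.muscle_lme <- function(x, ...) {
  cat(sprintf("<muscle_lme> %s ~ group * %s + (1 | subject)\n", x$feature, x$within))
  print(as.data.frame(x$anova), row.names = FALSE)
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n", x$r2[1], x$r2[2]))
  invisible(x)
}

#' Backward-stepwise mixed model for a kinematic outcome
#'
#' Starts from `outcome ~ group + factor1 + ... + (1 | subject)` and
#' removes fixed effects backward to optimize AIC (models compared under
#' ML), keeping the random intercept throughout; the final model is refit
#' with REML and summarized with Nakagawa marginal/conditional R-squared.
#'
#' @param data Records with the outcome, `group`, factor score columns and
#'   `subject_id`.
#' @param outcome Name of the kinematic outcome column.
#' @param predictors Candidate fixed effects (default: `group` plus all
#'   `factor*` columns present).
#' @return An object of class `muscle_stepwise_lme`: selected predictors,
#'   coefficient table of the final REML fit, `r2`, and the AIC trace.
#' @export
stepwise_lme <- function(data, outcome, predictors = NULL) {
  if (is.null(predictors)) {
    predictors <- c(
      intersect("group", colnames(data)),
      sort(grep("^factor[0-9]+$", colnames(data), value = TRUE))
    )
  }
  stopifnot(outcome %in% colnames(data), length(predictors) >= 1L)
  fit_ml <- function(terms) {
    rhs <- if (length(terms)) paste(terms, collapse = " + ") else "1"
    fml <- as.formula(paste0(outcome, " ~ ", rhs, " + (1 | subject_id)"))
    tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(fml, data = data, REML = FALSE,
                   control = lme4::lmerControl(check.conv.singular = "ignore"))
      )),
      error = function(e) NULL
    )
  }
  current <- predictors
  m <- fit_ml(current)
  if (is.null(m)) abort("initial stepwise model failed to converge.")
  trace <- tibble::tibble(step = 0L, dropped = NA_character_, aic = AIC(m))
  step_i <- 0L
  repeat {
    if (!length(current)) break
    cand <- lapply(current, function(tm) fit_ml(setdiff(current, tm)))
    aics <- vapply(cand, function(mm) if (is.null(mm)) Inf else AIC(mm), numeric(1))
    if (all(is.infinite(aics))) {
      warn("all single-term deletions failed to converge; stopping.")
      break
    }
    best <- which.min(aics)
    if (aics[best] >= AIC(m)) break
    step_i <- step_i + 1L
    trace <- dplyr::bind_rows(trace, tibble::tibble(
      step = step_i, dropped = current[best], aic = aics[best]
    ))
    m <- cand[[best]]
    current <- setdiff(current, current[best])
  }
  rhs <- if (length(current)) paste(current, collapse = " + ") else "1"
  final <- lmerTest::lmer(
    as.formula(paste0(outcome, " ~ ", rhs, " + (1 | subject_id)")),
    data = data, REML = TRUE
  )
  cf <- as.data.frame(summary(final)$coefficients)
  coefs <- tibble::tibble(
    term = rownames(cf), estimate = cf$Estimate, std.error = cf$`Std. Error`,
    statistic = cf$`t value`, df = cf$df, p.value = cf$`Pr(>|t|)`
  )
  structure(
    list(model = final, outcome = outcome, selected = current,
         coefficients = coefs, r2 = r2_nakagawa(final), trace = trace),
    class = "muscle_stepwise_lme"
  )
}

#' @export
print.muscle_stepwise_lme <- function(x, ...) {
  cat(sprintf("<muscle_stepwise_lme> %s ~ %s + (1 | subject)\n", x$outcome,
              if (length(x$selected)) paste(x$selected, collapse = " + ") else "1"))
  cat(sprintf("R2 marginal %.3f, conditional %.3f\n", x$r2[1], x$r2[2]))
  invisible(x)
}

#' F1 score from precision and recall
#'
#' Harmonic mean `2 P R / (P + R)`.
#'
#' @param precision,recall Values in `[0, 1]`.
#' @return F1 in `[0, 1]` (`NA` when both are 0).
#' @export
f1_score <- function(precision, recall) {
  ifelse(precision + recall > 0, 2 * precision * recall / (precision + recall),
         NA_real_)
}

# Stratified fold assignment; grouped by subject (no leakage) or per
# record. Returns an integer fold id per row.
assign_folds <- function(y, subject, folds, grouping) {
  n <- length(y)
  fold <- integer(n)
  if (grouping == "subject") {
    su <- tibble::tibble(subject = subject, y = y)
    su <- dplyr::distinct(su)
    for (cls in levels(y)) {
      subs <- sample(su$subject[su$y == cls])
      if (length(subs) < folds) {
        abort("stratified subject-grouped folds impossible: a class has fewer subjects than folds.")
      }
      f <- rep_len(seq_len(folds), length(subs))
      for (i in seq_along(subs)) fold[subject == subs[i]] <- f[i]
    }
  } else {
    for (cls in levels(y)) {
      idx <- sample(which(y == cls))
      if (length(idx) < folds) {
        abort("stratified folds impossible: a class has fewer records than folds.")
      }
      fold[idx] <- rep_len(seq_len(folds), length(idx))
    }
  }
  fold
}

# P(positive class) out-of-fold scores for one algorithm.
oof_scores <- function(x_train, y_train, x_test, algorithm, positive) {
  if (algorithm == "rf") {
    m <- randomForest::randomForest(x_train, y_train, ntree = 500)
    predict(m, x_test, type = "prob")[, positive]
  } else if (algorithm == "svm") {
    d2 <- as.vector(stats::dist(scale(x_train)))^2
    gamma <- 1 / (2 * max(median(d2), 1e-6))
    m <- e1071::svm(x_train, y_train, kernel = "radial", gamma = gamma,
                    cost = 1, probability = TRUE)
    attr(predict(m, x_test, probability = TRUE), "probabilities")[, positive]
  } else if (algorithm == "knn") {
    mu <- colMeans(x_train); sg <- apply(x_train, 2, sd)
    sg[sg <= 0] <- 1
    zt <- scale(x_train, mu, sg); zs <- scale(x_test, mu, sg)
    pr <- class::knn(zt, zs, y_train, k = 5, prob = TRUE)
    p_win <- attr(pr, "prob")
    ifelse(pr == positive, p_win, 1 - p_win)
  } else {
    abort(sprintf("unknown algorithm '%s'.", algorithm))
  }
}

#' Repeated cross-validated classification of factor scores
#'
#' Classifies ALS vs control records from factor scores with a random
#' forest (500 trees), a radial-kernel SVM (kernel width from the
#' median-distance heuristic, unit cost) or k-nearest neighbours (k = 5,
#' standardized inputs), under stratified five-fold cross-validation
#' repeated 10 times. Out-of-fold predicted probabilities are pooled per
#' repeat; precision, recall, F1 (threshold 0.5) and AUC are averaged
#' over repeats. Folds are grouped by subject by default so sentences of
#' one subject never span train and test.
#'
#' @param data Records with factor score columns (`factor1`, ...),
#'   `group` and `subject_id`.
#' @param algorithm `"rf"`, `"svm"` or `"knn"`.
#' @param folds,repeats Cross-validation design (default 5 x 10).
#' @param seed Seed for fold assignment.
#' @param grouping `"subject"` (grouped folds, default) or `"record"`.
#' @param positive Positive class label (default `"ALS"`).
#' @return An object of class `classifier_report`: `metrics` (one-row
#'   tibble: auc, f1, precision, recall), `per_repeat`, `roc` (pooled
#'   ROC points), `fold_assignments`, `algorithm`, `seed`.
#' @export
classify_factors <- function(data, algorithm = c("rf", "svm", "knn"),
                             folds = 5L, repeats = 10L, seed = NULL,
                             grouping = c("subject", "record"),
                             positive = "ALS") {
  algorithm <- match.arg(algorithm)
  grouping <- match.arg(grouping)
  score_cols <- sort(grep("^factor[0-9]+$", colnames(data), value = TRUE))
  if (!length(score_cols)) abort("no factor score columns (`factor1`, ...) found.")
  y <- factor(data$group)
  if (nlevels(y) < 2L) abort("need 2 classes present.")
  if (!positive %in% levels(y)) abort(sprintf("positive class '%s' not present.", positive))
  x <- as.matrix(data[score_cols])
  subject <- if ("subject_id" %in% colnames(data)) data$subject_id else seq_len(nrow(data))
  with_seed(seed, {
    assignments <- matrix(0L, nrow(x), repeats)
    per_rep <- purrr::map(seq_len(repeats), function(rep_i) {
      fold <- assign_folds(y, subject, folds, grouping)
      assignments[, rep_i] <<- fold
      score <- numeric(nrow(x))
      for (f in seq_len(folds)) {
        te <- fold == f
        if (length(unique(y[!te])) < 2L) abort("a training fold lost a class.")
        score[te] <- oof_scores(x[!te, , drop = FALSE], y[!te],
                                x[te, , drop = FALSE], algorithm, positive)
      }
      pred <- score >= 0.5
      truth <- y == positive
      tp <- sum(pred & truth); fp <- sum(pred & !truth); fn <- sum(!pred & truth)
      precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
      recall <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
      f1 <- if (isTRUE(precision + recall > 0)) {
        2 * precision * recall / (precision + recall)
      } else NA_real_
      auc <- as.numeric(pROC::auc(pROC::roc(truth, score, quiet = TRUE,
                                            direction = "<", levels = c(FALSE, TRUE))))
      list(metrics = tibble::tibble(repeat_id = rep_i, auc = auc, f1 = f1,
                                    precision = precision, recall = recall),
           score = score)
    })
    per_repeat <- dplyr::bind_rows(purrr::map(per_rep, "metrics"))
    pooled <- unlist(purrr::map(per_rep, "score"))
    truth_all <- rep(y == positive, repeats)
    roc_obj <- pROC::roc(truth_all, pooled, quiet = TRUE, direction = "<",
                         levels = c(FALSE, TRUE))
    prec <- mean(per_repeat$precision, na.rm = TRUE)
    rec <- mean(per_repeat$recall, na.rm = TRUE)
    structure(
      list(metrics = tibble::tibble(
             algorithm = algorithm,
             auc = mean(per_repeat$auc),
             f1 = f1_score(prec, rec),
             precision = prec,
             recall = rec
           ),
           per_repeat = per_repeat,
           roc = tibble::tibble(specificity = roc_obj$specificities,
                                sensitivity = roc_obj$sensitivities),
           fold_assignments = assignments,
           algorithm = algorithm, folds = folds, repeats = repeats,
           grouping = grouping, seed = seed),
      class = "classifier_report"
    )
  })
}

#' @export
print.classifier_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<classifier_report> %s (%d-fold x %d, %s-wise): AUC %.3f, F1 %.3f, precision %.3f, recall %.3f\n",
              toupper(x$algorithm), x$folds, x$repeats, x$grouping,
              m$auc, m$f1, m$precision, m$recall))
  invisible(x)
}

#' Run all three classifiers
#'
#' @inheritParams classify_factors
#' @return Named list of `classifier_report` objects (rf, svm, knn).
#' @export
classify_all <- function(data, folds = 5L, repeats = 10L, seed = NULL,
                         grouping = "subject") {
  algs <- c("rf", "svm", "knn")
  setNames(lapply(seq_along(algs), function(i) {
    classify_factors(data, algs[i], folds, repeats,
                     seed = if (is.null(seed)) NULL else derive_seed(seed, i),
                     grouping = grouping)
  }), algs)
}
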