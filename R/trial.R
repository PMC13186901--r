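#' Construct a virtual-trial dataset
#'
#' @param X Numeric feature matrix (subjects by biomarkers), complete.
#' @param y Class labels coercible to 0/1 (1 = diabetic kidney disease,
#'   0 = hypertensive kidney disease).
#' @param meta Optional per-subject metadata data frame (sex, age group).
#' @return An object of class `trial_dataset`.
#' @export
trial_dataset <- function(X, y, meta = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  stopifnot(nrow(X) == length(y))
  if (anyNA(X)) {
    bad <- colnames(X)[colSums(is.na(X)) > 0]
    stop("missing feature values in: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (length(unique(y)) < 2) {
    stop("both classes must be present", call. = FALSE)
  }
  structure(list(X = X, y = y, meta = meta), class = "trial_dataset")
}

# run expr with a private RNG stream, restoring the caller's stream
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Maximum-likelihood fit of the linear log-odds model
#'
#' Plain logistic regression via iteratively reweighted least squares.
#' When the data are perfectly separated (unbounded likelihood), a small
#' ridge penalty is applied so the coefficients stay finite; a message
#' records the fallback.
#'
#' @param X Feature matrix (already standardized by the caller for
#'   comparable coefficients).
#' @param y 0/1 labels, both classes present.
#' @param ridge Penalty used only on detected separation.
#' @return A list with `coefficients` (named, without intercept),
#'   `intercept`, `separable` (logical).
#' @export
fit_linear_logodds <- function(X, y, ridge = 1e-4) {
  X <- as.matrix(X)
  if (length(unique(y)) < 2) stop("single class in y", call. = FALSE)
  keep <- apply(X, 2, stats::sd) > 0
  if (!all(keep)) {
    warning("dropping zero-variance feature(s): ",
            paste(colnames(X)[!keep], collapse = ", "), call. = FALSE)
    X <- X[, keep, drop = FALSE]
  }
  fit <- suppressWarnings(stats::glm.fit(cbind(1, X), y,
                                         family = stats::binomial()))
  separable <- !fit$converged || any(abs(fit$coefficients[-1]) > 30)
  if (separable) {
    # penalized IRLS: (X'WX + lambda I) beta = X'W z
    Xd <- cbind(1, X)
    beta <- rep(0, ncol(Xd))
    pen <- diag(c(0, rep(ridge, ncol(X))))
    for (it in 1:50) {
      eta <- drop(Xd %*% beta)
      p <- 1 / (1 + exp(-eta))
      w <- pmax(p * (1 - p), 1e-10)
      z <- eta + (y - p) / w
      beta_new <- solve(crossprod(Xd, w * Xd) + pen, crossprod(Xd, w * z))
      if (max(abs(beta_new - beta)) < 1e-8) { beta <- drop(beta_new); break }
      beta <- drop(beta_new)
    }
    coefs <- beta
  } else {
    coefs <- fit$coefficients
  }
  out_coef <- stats::setNames(rep(0, sum(!keep) + sum(keep)),
                              c(colnames(X), names(keep)[!keep]))
  out_coef[colnames(X)] <- coefs[-1]
  list(coefficients = out_coef, intercept = unname(coefs[1]),
       separable = separable)
}

#' Area under the ROC curve
#'
#' Computed as the normalized Mann-Whitney U statistic with ties counted
#' one half.
#'
#' @param scores Numeric classifier scores (higher = class 1).
#' @param labels 0/1 labels.
#' @return AUC in `[0, 1]`.
#' @export
auc_roc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L)
  n0 <- sum(labels == 0L)
  if (n1 == 0 || n0 == 0) stop("both classes required", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Repeated stratified holdout evaluation of a biomarker set
#'
#' Per iteration: a stratified random 70/30 split, feature
#' standardization on the training fold, a [fit_linear_logodds()] fit, and
#' validation AUC plus accuracy at a probability threshold of 0.5.
#'
#' @param dataset A [trial_dataset()].
#' @param biomarkers Character vector of feature (column) names, or NULL
#'   for all.
#' @param n_iter Number of random splits.
#' @param train_frac Training fraction.
#' @param seed Integer seed; results are deterministic given the seed.
#' @return A list with `auc` (mean), `accuracy` (mean), `auc_iter`,
#'   `accuracy_iter`, `coefficients` (mean standardized coefficients) and
#'   `biomarkers`.
#' @export
repeated_holdout <- function(dataset, biomarkers = NULL, n_iter = 50,
                             train_frac = 0.70, seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  X <- dataset$X
  if (!is.null(biomarkers)) {
    missing_b <- setdiff(biomarkers, colnames(X))
    if (length(missing_b) > 0) {
      stop("unknown biomarker(s): ", paste(missing_b, collapse = ", "),
           call. = FALSE)
    }
    X <- X[, biomarkers, drop = FALSE]
  }
  y <- dataset$y
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  n1_tr <- max(1L, round(train_frac * length(i1)))
  n0_tr <- max(1L, round(train_frac * length(i0)))
  if (n1_tr >= length(i1) || n0_tr >= length(i0)) {
    stop("too few subjects per class for a ", 1 - train_frac,
         " validation fraction", call. = FALSE)
  }
  .with_seed(seed, {
    aucs <- accs <- numeric(n_iter)
    coef_sum <- stats::setNames(numeric(ncol(X)), colnames(X))
    for (k in seq_len(n_iter)) {
      tr <- c(sample(i1, n1_tr), sample(i0, n0_tr))
      va <- setdiff(seq_along(y), tr)
      mu <- colMeans(X[tr, , drop = FALSE])
      sg <- apply(X[tr, , drop = FALSE], 2, stats::sd)
      sg[sg == 0] <- 1
      Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
      fit <- suppressWarnings(
        fit_linear_logodds(Xs[tr, , drop = FALSE], y[tr]))
      eta <- drop(Xs[va, , drop = FALSE] %*% fit$coefficients) + fit$intercept
      p <- 1 / (1 + exp(-eta))
      aucs[k] <- auc_roc(eta, y[va])
      accs[k] <- mean((p > 0.5) == (y[va] == 1L))
      coef_sum <- coef_sum + fit$coefficients
    }
    list(auc = mean(aucs), accuracy = mean(accs), auc_iter = aucs,
         accuracy_iter = accs, coefficients = coef_sum / n_iter,
         biomarkers = colnames(X))
  })
}

#' Pearson correlation matrix of the biomarkers
#'
#' @param dataset A [trial_dataset()].
#' @return A list with `r` (correlation matrix, unit diagonal), and
#'   `order` (hierarchical-clustering ordering of the columns for
#'   plotting). Zero-variance columns yield `NA` rows/columns with a
#'   warning.
#' @export
correlation_matrix <- function(dataset) {
  stopifnot(inherits(dataset, "trial_dataset"), nrow(dataset$X) >= 3)
  X <- dataset$X
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0)) {
    warning("zero-variance biomarker(s), correlations undefined: ",
            paste(colnames(X)[sds == 0], collapse = ", "), call. = FALSE)
  }
  r <- suppressWarnings(stats::cor(X))
  ok <- sds > 0
  ord <- seq_len(ncol(X))
  if (sum(ok) > 2) {
    hc <- stats::hclust(stats::as.dist(1 - abs(r[ok, ok])), method = "average")
    ord <- c(which(ok)[hc$order], which(!ok))
  }
  list(r = r, order = ord)
}

#' The clinically accessible ("common") biomarker vocabulary
#'
#' Excludes pressure- and PWV-derived biomarkers, which are not measurable
#' with routine Doppler ultrasound or PC-MRI.
#'
#' @param all_names Candidate feature names.
#' @return Subset of `all_names`.
#' @export
common_biomarker_group <- function(all_names) {
  all_names[!grepl("Pressure|PWV", all_names)]
}

#' Random-capped search over biomarker combinations
#'
#' For each dimensionality, evaluates either all combinations (when their
#' count does not exceed `cap_per_dim`) or a seeded uniform sample of
#' distinct combinations, ranks them by mean holdout AUC, and summarises
#' the biomarkers appearing in the top performing combinations.
#'
#' @param dataset A [trial_dataset()].
#' @param group "full" (all features) or "common" (see
#'   [common_biomarker_group()]).
#' @param dims Integer vector of combination sizes (2..25).
#' @param cap_per_dim Maximum combinations evaluated per dimension.
#' @param n_top Size of the top list (100 in the headline analyses).
#' @param auc_threshold Only combinations above this AUC enter the top
#'   list.
#' @param n_iter,train_frac Passed to [repeated_holdout()].
#' @param seed Integer seed.
#' @return A list per dimension with `results` (data frame: biomarkers,
#'   auc, accuracy), `top` (top list), `frequency` (named counts of
#'   biomarkers in the top list), `top10` and `coefficients` (mean
#'   standardized coefficient of each top-10 biomarker over the top
#'   combinations containing it).
#' @export
combination_search <- function(dataset, group = c("full", "common"),
                               dims = 2:3, cap_per_dim = 5000, n_top = 100,
                               auc_threshold = 0.8, n_iter = 50,
                               train_frac = 0.70, seed = 1) {
  group <- match.arg(group)
  stopifnot(inherits(dataset, "trial_dataset"))
  vocab <- colnames(dataset$X)
  if (group == "common") vocab <- common_biomarker_group(vocab)
  p <- length(vocab)
  out <- list()
  for (d in dims) {
    if (d > p) stop("dimension ", d, " exceeds vocabulary size ", p,
                    call. = FALSE)
    n_comb <- choose(p, d)
    combos <- if (n_comb <= cap_per_dim) {
      utils::combn(vocab, d, simplify = FALSE)
    } else {
      .with_seed(seed + d, {
        seen <- new.env(hash = TRUE)
        res <- vector("list", cap_per_dim)
        got <- 0L
        while (got < cap_per_dim) {
          cand <- sort(sample.int(p, d))
          key <- paste(cand, collapse = ",")
          if (is.null(seen[[key]])) {
            seen[[key]] <- TRUE
            got <- got + 1L
            res[[got]] <- vocab[cand]
          }
        }
        res
      })
    }
    evals <- lapply(seq_along(combos), function(i) {
      rh <- repeated_holdout(dataset, combos[[i]], n_iter = n_iter,
                             train_frac = train_frac, seed = seed + 7 * i)
      list(biomarkers = combos[[i]], auc = rh$auc, accuracy = rh$accuracy,
           coefficients = rh$coefficients)
    })
    auc_v <- vapply(evals, `[[`, 0, "auc")
    ord <- order(auc_v, decreasing = TRUE)
    top_idx <- ord[auc_v[ord] > auc_threshold]
    top_idx <- utils::head(top_idx, n_top)
    freq <- sort(table(unlist(lapply(evals[top_idx], `[[`, "biomarkers"))),
                 decreasing = TRUE)
    top10 <- utils::head(names(freq), 10)
    coefs <- vapply(top10, function(b) {
      vals <- unlist(lapply(evals[top_idx], function(e) {
        if (b %in% e$biomarkers) e$coefficients[[b]] else NULL
      }))
      mean(vals)
    }, 0)
    results <- data.frame(
      biomarkers = vapply(evals, function(e) paste(e$biomarkers, collapse = " + "), ""),
      auc = auc_v,
      accuracy = vapply(evals, `[[`, 0, "accuracy"),
      stringsAsFactors = FALSE)
    out[[as.character(d)]] <- list(
      dimension = d, results = results[ord, ],
      top = results[top_idx, ],
      frequency = freq, top10 = top10, coefficients = coefs)
  }
  out
}

#' Univariate AUC screen across biomarkers and locations
#'
#' Evaluates every biomarker one at a time with [repeated_holdout()].
#'
#' @param dataset A [trial_dataset()] whose column names follow
#'   `location.name`.
#' @param n_iter,train_frac,seed Passed to [repeated_holdout()].
#' @return Data frame with `feature`, `location`, `name`, `auc`,
#'   `accuracy`, sorted by AUC.
#' @export
univariate_screen <- function(dataset, n_iter = 50, train_frac = 0.70,
                              seed = 1) {
  stopifnot(inherits(dataset, "trial_dataset"))
  feats <- colnames(dataset$X)
  res <- lapply(seq_along(feats), function(i) {
    rh <- repeated_holdout(dataset, feats[i], n_iter = n_iter,
                           train_frac = train_frac, seed = seed + i)
    c(auc = rh$auc, accuracy = rh$accuracy)
  })
  res <- do.call(rbind, res)
  has_loc <- grepl(".", feats, fixed = TRUE)
  loc <- ifelse(has_loc, sub("\\..*$", "", feats), NA_character_)
  nm <- ifelse(has_loc, sub("^[^.]*\\.", "", feats), feats)
  out <- data.frame(feature = feats, location = loc, name = nm,
                    auc = res[, "auc"], accuracy = res[, "accuracy"],
                    stringsAsFactors = FALSE)
  out[order(out$auc, decreasing = TRUE), ]
}
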