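#' Train a subjective cone-type classifier
#'
#' Fits a linear soft-margin support vector machine to cones' mean positions
#' in the uniform appearance diagram, labeled with their objectively
#' (densitometry-) determined spectral type. A single straight boundary in
#' the UAD separates reddish-yellow (L) from green-blue (M) percepts; nothing
#' in the data motivates a nonlinear kernel. No class reweighting is applied,
#' so the boundary inherits the training L:M ratio (about 2:1 in most
#' trichromats) — accuracy on mosaics with very different ratios is untested
#' territory.
#'
#' @param uad_xy Two-column matrix or data frame of mean (x, y) per cone.
#' @param types Factor or character labels, "L"/"M", aligned with rows.
#' @param cost Soft-margin constant (default 1).
#' @return A `subjective_classifier`: list with the fitted svm, the implied
#'   boundary `weights` (w1, w2) and `offset` (decision = w . xy - offset,
#'   positive = L), and training metadata.
#' @export
train_classifier <- function(uad_xy, types, cost = 1) {
  uad_xy <- as.matrix(uad_xy)
  types <- as.character(types)
  stopifnot(ncol(uad_xy) == 2, nrow(uad_xy) == length(types))
  if (!all(types %in% c("L", "M"))) stop("labels must be L or M")
  if (length(unique(types)) < 2 || min(table(types)) < 3) {
    stop("need >= 3 cones of each class")
  }
  df <- data.frame(x = uad_xy[, 1], y = uad_xy[, 2],
                   type = factor(types, levels = c("L", "M")))
  fit <- e1071::svm(type ~ x + y, data = df, kernel = "linear", cost = cost,
                    scale = FALSE)
  w <- drop(t(fit$coefs) %*% as.matrix(fit$SV))
  rho <- fit$rho
  # canonicalize the decision sign so positive always means L
  dec <- drop(as.matrix(df[, c("x", "y")]) %*% w) - rho
  if (mean((dec >= 0) == (stats::predict(fit, df) == "L")) < 0.5) {
    w <- -w; rho <- -rho
  }
  structure(list(svm = fit, weights = w, offset = rho,
                 n = nrow(df), label_counts = table(df$type),
                 cost = cost),
            class = "subjective_classifier")
}

#' Predict cone types from mean UAD positions
#'
#' Cones on the L side of the learned boundary are labeled L, the other side
#' M; a point exactly on the boundary goes to L (fixed tie-break).
#'
#' @param classifier A `subjective_classifier`.
#' @param uad_xy Two-column matrix/data frame of (x, y) positions.
#' @return Character vector of "L"/"M".
#' @export
predict_types <- function(classifier, uad_xy) {
  uad_xy <- as.matrix(uad_xy)
  dec <- drop(uad_xy %*% classifier$weights) - classifier$offset
  ifelse(dec >= 0, "L", "M")
}

#' Agreement between subjective and objective classification
#'
#' Percent agreement, Cohen's kappa with its large-sample null p-value, and a
#' bootstrap SE of the agreement (resampling cones with replacement).
#'
#' @param predicted,objective Aligned label vectors.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed Seed for the bootstrap.
#' @return List with `agreement_percent`, `n_agree`, `n`, `kappa`,
#'   `kappa_p`, `boot_se` (percentage points).
#' @export
agreement <- function(predicted, objective, n_boot = 1000, seed = 1) {
  predicted <- as.character(predicted)
  objective <- as.character(objective)
  if (length(predicted) != length(objective)) {
    stop("label vectors must be the same length")
  }
  n <- length(predicted)
  n_agree <- sum(predicted == objective)
  kp <- cohens_kappa(predicted, objective)
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      ix <- sample.int(n, n, replace = TRUE)
      mean(predicted[ix] == objective[ix]) * 100
    }, 0)
  })
  list(agreement_percent = 100 * n_agree / n,
       n_agree = n_agree, n = n,
       kappa = kp$kappa, kappa_p = kp$p,
       boot_se = stats::sd(boot))
}

#' Cohen's kappa for two label sequences
#'
#' kappa = (p_o - p_e) / (1 - p_e), with p_e the chance agreement expected
#' from the marginal label frequencies. The p-value is the large-sample
#' normal test of kappa = 0 with the standard null variance (Fleiss).
#'
#' @param a,b Aligned label vectors.
#' @return List `kappa`, `p`.
#' @export
cohens_kappa <- function(a, b) {
  lv <- union(unique(a), unique(b))
  a <- factor(a, levels = lv); b <- factor(b, levels = lv)
  n <- length(a)
  tab <- table(a, b) / n
  p_o <- sum(diag(tab))
  pr <- rowSums(tab); pc <- colSums(tab)
  p_e <- sum(pr * pc)
  kappa <- (p_o - p_e) / (1 - p_e)
  # null SE of kappa (Fleiss, Cohen & Everitt 1969)
  se0 <- sqrt((p_e + p_e^2 - sum(pr * pc * (pr + pc))) / (n * (1 - p_e)^2))
  z <- kappa / se0
  list(kappa = kappa, p = 2 * stats::pnorm(-abs(z)))
}

#' Leave-one-out agreement of the subjective classifier
#'
#' Each cone is predicted by a classifier trained on all other cones; useful
#' because resubstitution accuracy is optimistic on small mosaics.
#'
#' @inheritParams train_classifier
#' @param ... Passed to [agreement()].
#' @return As [agreement()], plus `protocol = "leave-one-out"`.
#' @export
loo_agreement <- function(uad_xy, types, cost = 1, ...) {
  uad_xy <- as.matrix(uad_xy)
  types <- as.character(types)
  pred <- vapply(seq_len(nrow(uad_xy)), function(i) {
    cl <- train_classifier(uad_xy[-i, , drop = FALSE], types[-i], cost = cost)
    predict_types(cl, uad_xy[i, , drop = FALSE])
  }, "")
  out <- agreement(pred, types, ...)
  out$protocol <- "leave-one-out"
  out
}

#' Persist a classifier boundary as structured text
#'
#' @param classifier A `subjective_classifier`.
#' @param path File path (JSON).
#' @export
write_classifier <- function(classifier, path) {
  jsonlite::write_json(list(weights = unname(classifier$weights),
                            offset = classifier$offset,
                            cost = classifier$cost,
                            n = classifier$n),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
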