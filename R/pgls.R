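#' Phylogenetic generalized least squares with Pagel's lambda
#'
#' Fits `response ~ predictors` by generalized least squares under a
#' Brownian-motion covariance derived from shared path lengths on the tree,
#' with Pagel's lambda multiplying the off-diagonal entries. Lambda is
#' estimated by maximizing the restricted (default) or full log-likelihood
#' over (1e-6, 1], or held fixed. Coefficients come from whitened least
#' squares; R-squared is 1 - RSS/TSS in whitened space against the
#' whitened intercept-only model at the fitted lambda, and the reported
#' p-value is the overall F-test of the model against that intercept-only
#' fit (two-sided).
#'
#' @param data Data frame / tibble with a `species` column (or species as
#'   the first column) matching the tree's tip labels.
#' @param response Name of the numeric response column.
#' @param predictors Character vector of predictor columns (categorical
#'   predictors are dummy-coded with the lexicographically first level as
#'   baseline).
#' @param tree Rooted "phylo" with branch lengths; tree and data are pruned
#'   to their common species.
#' @param lambda `"REML"` (default), `"ML"`, or a fixed value in \[0, 1\].
#' @return Object of class `pgls_fit` with `tidy()`, `glance()` and
#'   `autoplot()` methods.
#' @export
pgls_fit <- function(data, response, predictors, tree,
                     lambda = "REML") {
  data <- as_tibble(data)
  if (!"species" %in% names(data)) names(data)[1] <- "species"
  keep_cols <- c("species", response, predictors)
  miss <- setdiff(keep_cols, names(data))
  if (length(miss) > 0) abort(paste0("missing column: ", miss[1]))
  data <- data[, keep_cols]
  common <- intersect(tree$tip.label, data$species)
  if (length(common) < 3) abort("need >= 3 species shared by tree and data")
  data <- data[match(common, data$species), , drop = FALSE]
  data <- data[complete.cases(data), , drop = FALSE]
  common <- data$species
  if (length(common) < 3) abort("need >= 3 species with complete data")
  tree <- ape::keep.tip(tree, common)
  V <- ape::vcv(tree)[common, common]
  y <- as.numeric(data[[response]])
  # treatment coding, lexicographic baseline
  df <- as.data.frame(data[, predictors, drop = FALSE])
  for (cc in names(df)) {
    if (!is.numeric(df[[cc]])) df[[cc]] <- factor(df[[cc]],
                                                  levels = sort(unique(df[[cc]])))
  }
  X <- model.matrix(stats::as.formula(paste("~", paste(predictors,
                                                       collapse = " + "))),
                    data = df)
  n <- length(y); p <- ncol(X)
  if (n < p + 1) abort("too few species for the number of parameters")
  if (qr(X)$rank < p) abort("singular design matrix")
  if (!is_ultrametric_safe(tree))
    warn("tree is not ultrametric; Brownian covariance taken as-is")

  fit_at <- function(lam, reml) {
    Vl <- V * lam
    diag(Vl) <- diag(V)
    ch <- tryCatch(chol(Vl), error = function(e) NULL)
    if (is.null(ch)) return(NULL)
    # whitening: t(L)^-1 with Vl = t(ch) %*% ch
    Wy <- backsolve(ch, y, transpose = TRUE)
    WX <- backsolve(ch, X, transpose = TRUE)
    qrx <- qr(WX)
    beta <- qr.coef(qrx, Wy)
    resid <- Wy - WX %*% beta
    rss <- sum(resid^2)
    logdetV <- 2 * sum(log(diag(ch)))
    if (reml) {
      XtX <- crossprod(WX)
      s2 <- rss / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * max(s2, 1e-12)) + logdetV +
                      determinant(XtX, logarithm = TRUE)$modulus[1] +
                      (n - p))
    } else {
      s2 <- rss / n
      ll <- -0.5 * (n * log(2 * pi * max(s2, 1e-12)) + logdetV + n)
    }
    list(beta = beta, rss = rss, s2 = s2, ll = ll, ch = ch, qrx = qrx,
         WX = WX, Wy = Wy)
  }

  reml <- FALSE
  if (is.character(lambda)) {
    mode <- match.arg(lambda, c("REML", "ML"))
    reml <- mode == "REML"
    ll_of <- function(l) {
      f <- fit_at(l, reml)
      if (is.null(f)) -1e300 else f$ll
    }
    opt <- optimize(ll_of, c(1e-6, 1), maximum = TRUE, tol = 1e-8)
    # compare with the boundary; optimize() can miss a boundary maximum
    cand <- c(opt$maximum, 1e-6, 1)
    lls <- vapply(cand, ll_of, numeric(1))
    lam <- cand[which.max(lls)]
  } else {
    if (lambda < 0 || lambda > 1) abort("lambda must be in [0, 1]")
    lam <- max(lambda, 0)
    mode <- "fixed"
  }
  ft <- fit_at(max(lam, 1e-12), reml)
  # intercept-only fit at the same lambda for TSS / F test
  Vl <- V * max(lam, 1e-12); diag(Vl) <- diag(V)
  ch <- ft$ch
  W1 <- backsolve(ch, matrix(1, n, 1), transpose = TRUE)
  Wy <- ft$Wy
  b0 <- sum(W1 * Wy) / sum(W1 * W1)
  tss <- sum((Wy - W1 * b0)^2)
  rss <- ft$rss
  r2 <- if (tss <= 1e-12 * max(1, sum(Wy^2))) 0 else 1 - rss / tss
  df1 <- p - 1; df2 <- n - p
  fstat <- if (df1 == 0 || rss <= 0) NA_real_
           else ((tss - rss) / df1) / (rss / df2)
  pval <- if (df1 == 0) NA_real_ else pf(fstat, df1, df2, lower.tail = FALSE)
  # coefficient table
  s2 <- rss / df2
  XtXi <- chol2inv(qr.R(ft$qrx))
  se <- sqrt(diag(XtXi) * s2)
  tval <- as.numeric(ft$beta) / se
  coefs <- tibble(term = colnames(X), estimate = as.numeric(ft$beta),
                  std_error = se, statistic = tval,
                  p_value = 2 * pt(abs(tval), df2, lower.tail = FALSE))
  structure(list(coefficients = coefs, lambda = lam, lambda_mode = mode,
                 r_squared = r2, fstatistic = fstat, df = c(df1, df2),
                 p_value = pval, n = n, sigma2 = s2,
                 logLik = ft$ll, response = response,
                 predictors = predictors,
                 fitted = as.numeric(X %*% ft$beta), y = y,
                 species = common),
            class = "pgls_fit")
}

is_ultrametric_safe <- function(tree) {
  if (is.null(tree$edge.length)) return(FALSE)
  isTRUE(tryCatch(ape::is.ultrametric(tree, tol = 1e-6),
                  error = function(e) TRUE))
}

#' @export
print.pgls_fit <- function(x, ...) {
  cat("pGLS fit: ", x$response, " ~ ",
      paste(x$predictors, collapse = " + "), "\n", sep = "")
  cat("lambda = ", signif(x$lambda, 4), " (", x$lambda_mode, "), R2 = ",
      signif(x$r_squared, 4), ", F(", x$df[1], ",", x$df[2], ") p = ",
      signif(x$p_value, 4), ", n = ", x$n, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' @export
tidy.pgls_fit <- function(x, ...) x$coefficients

#' @export
glance.pgls_fit <- function(x, ...) {
  tibble(lambda = x$lambda, r_squared = x$r_squared,
         statistic = x$fstatistic, p_value = x$p_value, n = x$n,
         sigma2 = x$sigma2, logLik = x$logLik,
         lambda_mode = x$lambda_mode)
}

#' Observed-versus-fitted plot of a pGLS fit
#' @param object A `pgls_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pgls_fit <- function(object, ...) {
  d <- tibble(fitted = object$fitted, observed = object$y)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fitted, y = .data$observed)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::labs(x = "fitted", y = "observed",
                  title = paste0("pGLS: ", object$response,
                                 " (lambda = ", signif(object$lambda, 3),
                                 ")")) +
    ggplot2::theme_minimal()
}

#' Pairwise pGLS correlation matrix of chemoreceptor family counts
#'
#' Regresses each family's complete-gene count on each other family's count
#' with [pgls_fit()], including the aggregate olfactory (OLR = OR + TAAR +
#' V1R + V2R) versus taste (TR = T1R + T2R) pair. Pairs with fewer than
#' three shared species are skipped with a warning.
#'
#' @param counts Tibble with a `species` column and one numeric column per
#'   family.
#' @param tree Rooted "phylo".
#' @param families Family columns to correlate.
#' @param alpha Significance flag threshold.
#' @return Tibble: `x`, `y`, `r_squared`, `p_value`, `lambda`, `n`,
#'   `significant`.
#' @export
family_count_correlations <- function(counts, tree,
                                      families = intersect(CHEMO_FAMILIES,
                                                           names(counts)),
                                      alpha = 0.05) {
  counts <- as_tibble(counts)
  if (!"species" %in% names(counts)) names(counts)[1] <- "species"
  olr <- intersect(c("OR", "TAAR", "V1R", "V2R"), names(counts))
  tr <- intersect(c("T1R", "T2R"), names(counts))
  if (length(olr) > 0 && length(tr) > 0) {
    counts$OLR <- rowSums(counts[, olr, drop = FALSE])
    counts$TR <- rowSums(counts[, tr, drop = FALSE])
  }
  pairs <- utils::combn(families, 2, simplify = FALSE)
  if ("OLR" %in% names(counts)) pairs <- c(pairs, list(c("OLR", "TR")))
  purrr::map(pairs, function(pr) {
    ft <- tryCatch(
      pgls_fit(counts, response = pr[2], predictors = pr[1], tree),
      error = function(e) {
        warn(paste0("pair ", pr[1], "-", pr[2], " skipped: ",
                    conditionMessage(e)))
        NULL
      })
    if (is.null(ft)) return(NULL)
    tibble(x = pr[1], y = pr[2], r_squared = ft$r_squared,
           p_value = ft$p_value, lambda = ft$lambda, n = ft$n,
           significant = !is.na(ft$p_value) && ft$p_value < alpha)
  }) |> bind_rows()
}

#' Diet category from trophic level
#'
#' Fish diet coding: trophic level <= 2.19 is herbivore, 2.2-2.79 omnivore,
#' >= 2.8 carnivore. Values are rounded to two decimals first so readings in
#' the open gaps land in the adjacent class.
#'
#' @param t Positive trophic level(s).
#' @return Character vector of `"herbivore"`, `"omnivore"`, `"carnivore"`.
#' @export
diet_from_trophic_level <- function(t) {
  if (any(!is.finite(t)) || any(t <= 0)) abort("trophic level must be > 0")
  t <- round(t, 2)
  dplyr::case_when(
    t <= 2.19 ~ "herbivore",
    t <= 2.79 ~ "omnivore",
    TRUE ~ "carnivore"
  )
}
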