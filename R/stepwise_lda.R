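#' Wilks' lambda for a two-class variable subset
#'
#' \eqn{\Lambda = \det(W)/\det(T)} where \eqn{W} is the pooled within-class
#' cross-product matrix and \eqn{T} the total cross-product matrix, both
#' about their respective means. \eqn{\Lambda = 1} means no between-class
#' separation; values near 0 mean strong separation.
#'
#' @param X Numeric matrix (rows = compounds, columns = variables).
#' @param y Binary labels, inhibitor = 1.
#' @return Lambda in (0, 1] (0 attainable when within-class variance
#'   vanishes while classes differ).
#' @export
wilks_lambda <- function(X, y) {
  X <- as.matrix(X)
  y <- as_binary(y)
  stopifnot(nrow(X) == length(y))
  if (min(table(y)) < 2L) stop("need at least 2 rows per class")
  sc <- scatter_matrices(X, y)
  ldT <- determinant(sc$T, logarithm = TRUE)
  if (ldT$sign <= 0 || !is.finite(ldT$modulus)) {
    qrT <- qr(sc$T)
    bad <- colnames(X)[qrT$pivot[qrT$rank + 1L]]
    stop(sprintf("total scatter matrix is singular (collinear variable: %s)",
                 if (is.null(bad) || is.na(bad)) "unknown" else bad))
  }
  ldW <- determinant(sc$W, logarithm = TRUE)
  if (ldW$sign <= 0 || !is.finite(ldW$modulus)) return(0)
  lambda <- exp(as.numeric(ldW$modulus - ldT$modulus))
  min(max(lambda, 0), 1)
}

# Pooled within-class (W) and total (T) cross-product matrices.
scatter_matrices <- function(X, y) {
  Xc <- sweep(X, 2L, colMeans(X))
  Tm <- crossprod(Xc)
  W <- matrix(0, ncol(X), ncol(X), dimnames = dimnames(Tm))
  for (g in c(0L, 1L)) {
    Xg <- X[y == g, , drop = FALSE]
    W <- W + crossprod(sweep(Xg, 2L, colMeans(Xg)))
  }
  list(W = W, T = Tm)
}

#' Partial F of one variable given the current selection
#'
#' The F-to-enter (variable outside the selection) or F-to-remove (variable
#' inside it) of stepwise discriminant analysis. With conditioning set of
#' size \eqn{p}, two groups and \eqn{n} rows,
#' \deqn{F = (n - 2 - p)\,(\Lambda_p/\Lambda_{p+1} - 1)}
#' on \eqn{(1, n - 2 - p)} degrees of freedom; with an empty conditioning
#' set this is the one-way ANOVA F of the variable.
#'
#' @param X Numeric matrix with column names.
#' @param y Binary labels.
#' @param variable Column name (or index) being tested.
#' @param selection Character vector of currently selected columns; if
#'   \code{variable} belongs to it the F-to-remove is computed (conditioning
#'   on the selection minus the variable).
#' @return List with \code{F}, \code{p_value}, \code{df1}, \code{df2}.
#' @export
partial_f <- function(X, y, variable, selection = character()) {
  X <- as.matrix(X)
  y <- as_binary(y)
  if (is.numeric(variable)) variable <- colnames(X)[variable]
  stopifnot(variable %in% colnames(X))
  cond <- setdiff(selection, variable)
  p <- length(cond)
  n <- nrow(X)
  df2 <- n - 2L - p
  if (df2 <= 0L) stop("model saturated: n - g - p degrees of freedom exhausted")
  lam_p <- if (p == 0L) 1 else wilks_lambda(X[, cond, drop = FALSE], y)
  lam_p1 <- wilks_lambda(X[, c(cond, variable), drop = FALSE], y)
  Fv <- if (lam_p1 <= 0) Inf else df2 * (lam_p / lam_p1 - 1)
  Fv <- max(Fv, 0)
  list(F = Fv, p_value = stats::pf(Fv, 1, df2, lower.tail = FALSE),
       df1 = 1L, df2 = df2)
}

#' Configuration for stepwise discriminant fitting
#'
#' @param f_enter Partial-F threshold to enter a variable (the study used
#'   0.5 and 2.0). Entry requires F strictly greater than the threshold.
#' @param f_remove Threshold below which a selected variable is removed;
#'   defaults to \code{f_enter} (the two are coupled unless overridden);
#'   must not exceed \code{f_enter}.
#' @param priors \code{"equal"} (default; counteracts class imbalance) or
#'   \code{"empirical"}.
#' @param max_steps Cap on the total number of enter/remove actions.
#' @param tolerance Minimum within-group tolerance (1 - R^2 of a candidate
#'   against the selected set) below which a candidate is skipped as
#'   collinear.
#' @return A list of class \code{"lda_fit_config"}.
#' @export
lda_fit_config <- function(f_enter = 2.0, f_remove = f_enter,
                           priors = c("equal", "empirical"),
                           max_steps = 1000L, tolerance = 1e-4) {
  priors <- match.arg(priors)
  stopifnot(f_enter > 0, f_remove > 0, f_remove <= f_enter, max_steps >= 1)
  structure(list(f_enter = f_enter, f_remove = f_remove, priors = priors,
                 max_steps = as.integer(max_steps), tolerance = tolerance),
            class = "lda_fit_config")
}

#' Forward stepwise linear discriminant analysis
#'
#' Two-class LDA with forward stepwise variable selection: at each step the
#' unselected variable with the largest partial F enters if that F exceeds
#' \code{f_enter}; afterwards any selected variable whose F-to-remove falls
#' below \code{f_remove} is removed. Iteration stops when no entry
#' qualifies, degrees of freedom are exhausted, or \code{max_steps} actions
#' have been taken. The final model is an ordinary two-class LDA on the
#' selected variables with the configured priors.
#'
#' Occupancy counts enter unstandardized; LDA decisions are invariant to
#' per-variable affine rescaling. When no variable qualifies the model is
#' empty and prediction falls back to the non-inhibitor class at posterior
#' 0.5 (the specificity-conserving tie-break).
#'
#' @param X Numeric matrix or data.frame of features (compounds x
#'   variables), or an [build_occupancy_matrix()] object.
#' @param y Binary labels (ignored when \code{X} is an occupancy matrix,
#'   which carries its own).
#' @param config An [lda_fit_config()].
#' @return Object of class \code{"stepwise_lda"}: selected variables (in
#'   entry order of the surviving set), class means, pooled covariance,
#'   discriminant coefficients/intercepts, priors, per-variable
#'   F-to-remove/p-values, and a step \code{trace} data.frame (action,
#'   variable, lambda before/after, partial F, p-value).
#' @export
fit_stepwise_lda <- function(X, y = NULL, config = lda_fit_config()) {
  if (inherits(X, "occupancy_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$counts
  }
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("V", seq_len(ncol(X)))
  y <- as_binary(y)
  stopifnot(nrow(X) == length(y))
  if (length(unique(y)) != 2L) stop("both classes must be present")
  n <- nrow(X); p_all <- ncol(X)
  vars <- colnames(X)

  sc <- scatter_matrices(X, y)
  W <- sc$W; Tm <- sc$T
  diagW <- diag(W); diagT <- diag(Tm)

  sel <- integer(0)     # column indices, in entry order
  banned <- integer(0)  # numerically collinear candidates
  steps <- 0L
  trace <- list()
  lambda_cur <- 1
  # Cholesky-based inverses of the selected blocks, refreshed per action
  refresh <- function(sel) {
    if (!length(sel)) return(list(Winv = NULL, Tinv = NULL, lambda = 1))
    cW <- chol(W[sel, sel, drop = FALSE])
    cT <- chol(Tm[sel, sel, drop = FALSE])
    list(Winv = chol2inv(cW), Tinv = chol2inv(cT),
         lambda = exp(2 * (sum(log(diag(cW))) - sum(log(diag(cT))))))
  }
  st <- refresh(sel)

  repeat {
    df2 <- n - 2L - length(sel)
    if (df2 <= 0L || steps >= config$max_steps) break
    cand <- setdiff(seq_len(p_all), c(sel, banned))
    if (!length(cand)) break
    # Schur complements of each candidate on the selected block
    if (length(sel)) {
      Wsc <- W[sel, cand, drop = FALSE]
      Tsc <- Tm[sel, cand, drop = FALSE]
      w_res <- diagW[cand] - colSums(Wsc * (st$Winv %*% Wsc))
      t_res <- diagT[cand] - colSums(Tsc * (st$Tinv %*% Tsc))
    } else {
      w_res <- diagW[cand]
      t_res <- diagT[cand]
    }
    tol <- ifelse(diagW[cand] > 0, w_res / diagW[cand], 0)
    ok <- tol >= config$tolerance & t_res > 1e-12 * pmax(diagT[cand], 1) &
      w_res > 0
    Fent <- rep(-Inf, length(cand))
    Fent[ok] <- pmax(df2 * (t_res[ok] / w_res[ok] - 1), 0)
    if (!any(ok) || max(Fent) <= config$f_enter) break
    # try candidates in decreasing-F order (ties: lowest column index);
    # a candidate whose entry makes the within block numerically
    # unfactorable is banned as collinear and the next one is tried
    entered <- FALSE
    for (b in order(Fent, decreasing = TRUE)) {
      if (Fent[b] <= config$f_enter) break
      j <- cand[b]
      st_try <- tryCatch(refresh(c(sel, j)), error = function(e) NULL)
      if (is.null(st_try)) {
        banned <- c(banned, j)
        next
      }
      lam_new <- lambda_cur * w_res[b] / t_res[b]
      trace[[length(trace) + 1L]] <- data.frame(
        step = steps + 1L, action = "enter", variable = vars[j],
        lambda_before = lambda_cur, lambda_after = lam_new,
        partial_F = Fent[b],
        p_value = stats::pf(Fent[b], 1, df2, lower.tail = FALSE),
        stringsAsFactors = FALSE)
      sel <- c(sel, j)
      lambda_cur <- lam_new
      steps <- steps + 1L
      st <- st_try
      entered <- TRUE
      break
    }
    if (!entered) break

    # removal sweep: drop the weakest variable while any F-to-remove
    # falls below the threshold
    repeat {
      if (length(sel) < 2L || steps >= config$max_steps) break
      df2r <- n - 1L - length(sel)  # conditioning set has |sel| - 1 variables
      Frem <- pmax(df2r * (diag(st$Winv) / diag(st$Tinv) - 1), 0)
      if (min(Frem) >= config$f_remove) break
      worst <- which.min(Frem)
      v <- sel[worst]
      sel_new <- sel[-worst]
      st_new <- tryCatch(refresh(sel_new), error = function(e) NULL)
      if (is.null(st_new)) break
      trace[[length(trace) + 1L]] <- data.frame(
        step = steps + 1L, action = "remove", variable = vars[v],
        lambda_before = lambda_cur, lambda_after = st_new$lambda,
        partial_F = Frem[worst],
        p_value = stats::pf(Frem[worst], 1, df2r, lower.tail = FALSE),
        stringsAsFactors = FALSE)
      sel <- sel_new
      st <- st_new
      lambda_cur <- st$lambda
      steps <- steps + 1L
    }
  }

  trace <- if (length(trace)) do.call(rbind, trace) else
    data.frame(step = integer(), action = character(), variable = character(),
               lambda_before = numeric(), lambda_after = numeric(),
               partial_F = numeric(), p_value = numeric())

  build_lda_model(X, y, vars[sel], config, trace, st)
}

# Refit plain two-class LDA on the selected variables and package the model.
build_lda_model <- function(X, y, selected, config, trace, st) {
  n <- nrow(X)
  priors <- if (config$priors == "equal") c(`0` = 0.5, `1` = 0.5) else
    c(`0` = mean(y == 0L), `1` = mean(y == 1L))
  if (!length(selected)) {
    return(structure(list(
      selected = character(0), priors = priors, config = config,
      trace = trace, n = n, means = NULL, pooled_cov = NULL,
      coefficients = NULL, intercepts = NULL, variable_stats = NULL,
      lambda = 1), class = "stepwise_lda"))
  }
  Xs <- X[, selected, drop = FALSE]
  mu0 <- colMeans(Xs[y == 0L, , drop = FALSE])
  mu1 <- colMeans(Xs[y == 1L, , drop = FALSE])
  sc <- scatter_matrices(Xs, y)
  Sigma <- sc$W / (n - 2)
  # invert via the same Cholesky route the selection used; the stepwise
  # tolerance keeps W factorable even when solve()'s rcond check balks
  SigInv <- chol2inv(chol(sc$W)) * (n - 2)
  coef0 <- drop(SigInv %*% mu0); names(coef0) <- selected
  coef1 <- drop(SigInv %*% mu1); names(coef1) <- selected
  int0 <- -0.5 * sum(mu0 * coef0) + log(priors["0"])
  int1 <- -0.5 * sum(mu1 * coef1) + log(priors["1"])

  # per-variable F-to-remove and p-value in the final model
  p_sel <- length(selected)
  df2r <- n - 1L - p_sel
  vstat <- NULL
  if (df2r > 0L) {
    Winv <- chol2inv(chol(sc$W))
    Tinv <- chol2inv(chol(sc$T))
    Frem <- pmax(df2r * (diag(Winv) / diag(Tinv) - 1), 0)
    vstat <- data.frame(variable = selected, F_to_remove = unname(Frem),
                        p_value = stats::pf(unname(Frem), 1, df2r,
                                            lower.tail = FALSE),
                        stringsAsFactors = FALSE)
  }
  structure(list(
    selected = selected, priors = priors, config = config, trace = trace,
    n = n, means = rbind(`0` = mu0, `1` = mu1), pooled_cov = Sigma,
    coefficients = cbind(`0` = coef0, `1` = coef1),
    intercepts = c(`0` = unname(int0), `1` = unname(int1)),
    variable_stats = vstat, lambda = st$lambda), class = "stepwise_lda")
}

#' @export
print.stepwise_lda <- function(x, ...) {
  cat(sprintf("stepwise_lda: %d variables selected (F > %g), n = %d, Wilks' lambda = %.4g\n",
              length(x$selected), x$config$f_enter, x$n, x$lambda))
  if (length(x$selected)) {
    cat("  ", paste(utils::head(x$selected, 8L), collapse = ", "),
        if (length(x$selected) > 8L) "..." else "", "\n")
  } else {
    cat("  empty model: predictions fall back to non-inhibitor at 0.5\n")
  }
  invisible(x)
}

#' Classify compounds with a fitted stepwise LDA model
#'
#' Linear discriminant scores \eqn{\delta_k(x) = x^T \Sigma^{-1}\mu_k -
#' \tfrac12 \mu_k^T \Sigma^{-1}\mu_k + \ln \pi_k} with shared pooled
#' covariance; posteriors are the normalized exponentiated scores. Ties
#' (posterior exactly 0.5) classify as non-inhibitor.
#'
#' @param object A \code{"stepwise_lda"} model.
#' @param newdata Matrix or data.frame containing at least the selected
#'   variables (extra columns ignored).
#' @param ... Unused.
#' @return A data.frame with columns \code{class} (0/1) and
#'   \code{p_positive} (posterior probability of the inhibitor class).
#' @export
predict.stepwise_lda <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!length(object$selected)) {
    return(data.frame(class = rep(0L, nrow(newdata)),
                      p_positive = rep(0.5, nrow(newdata))))
  }
  missing <- setdiff(object$selected, colnames(newdata))
  if (length(missing)) {
    stop(sprintf("newdata lacks selected variables: %s",
                 paste(missing, collapse = ", ")))
  }
  Xs <- newdata[, object$selected, drop = FALSE]
  storage.mode(Xs) <- "double"
  scores <- Xs %*% object$coefficients +
    matrix(object$intercepts, nrow(Xs), 2L, byrow = TRUE)
  m <- pmax(scores[, 1L], scores[, 2L])
  p1 <- exp(scores[, 2L] - m) / (exp(scores[, 1L] - m) + exp(scores[, 2L] - m))
  data.frame(class = as.integer(p1 > 0.5), p_positive = unname(p1))
}

#' Per-bin report for a fitted SDAR model
#'
#' For each selected bin: the class mean occupancies (scaled by 100, so 100
#' means one shift in the range per compound) and the p-value of the bin's
#' F-to-remove in the final model.
#'
#' @param model A \code{"stepwise_lda"} fitted on \code{occ}.
#' @param occ The [build_occupancy_matrix()] the model was trained on.
#' @return data.frame: bin, mean occupancy per class, model p-value.
#' @export
bin_report <- function(model, occ) {
  stopifnot(inherits(model, "stepwise_lda"), inherits(occ, "occupancy_matrix"))
  cm <- class_mean_occupancy(occ)
  out <- cm[cm$bin %in% model$selected, , drop = FALSE]
  if (!is.null(model$variable_stats)) {
    out$p_value <- model$variable_stats$p_value[
      match(out$bin, model$variable_stats$variable)]
  } else {
    out$p_value <- NA_real_
  }
  rownames(out) <- NULL
  out
}

# -- serialization ----------------------------------------------------------

#' Write / read a stepwise LDA model as JSON
#' @param model A \code{"stepwise_lda"} object.
#' @param path File path.
#' @return \code{read_stepwise_lda} returns the restored model.
#' @export
write_stepwise_lda <- function(model, path) {
  stopifnot(inherits(model, "stepwise_lda"))
  payload <- list(
    type = "stepwise_lda", selected = model$selected,
    priors = as.list(model$priors), n = model$n, lambda = model$lambda,
    config = unclass(model$config),
    means = if (is.null(model$means)) NULL else as.data.frame(model$means),
    pooled_cov = model$pooled_cov, coefficients = model$coefficients,
    intercepts = as.list(model$intercepts), variable_stats = model$variable_stats,
    trace = model$trace)
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_stepwise_lda
#' @export
read_stepwise_lda <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(identical(j$type, "stepwise_lda"))
  sel <- as.character(j$selected)
  cfg <- structure(j$config, class = "lda_fit_config")
  cfg$max_steps <- as.integer(cfg$max_steps)
  m <- list(
    selected = sel,
    priors = c(`0` = j$priors[["0"]], `1` = j$priors[["1"]]),
    config = cfg, trace = as.data.frame(j$trace), n = as.integer(j$n),
    means = if (length(sel)) {
      mm <- as.matrix(j$means); dimnames(mm) <- list(c("0", "1"), sel); mm
    } else NULL,
    pooled_cov = if (length(sel)) {
      pc <- matrix(unlist(j$pooled_cov), length(sel), length(sel),
                   dimnames = list(sel, sel)); pc
    } else NULL,
    coefficients = if (length(sel)) {
      cf <- matrix(unlist(j$coefficients), length(sel), 2L,
                   dimnames = list(sel, c("0", "1"))); cf
    } else NULL,
    intercepts = c(`0` = j$intercepts[["0"]], `1` = j$intercepts[["1"]]),
    variable_stats = if (is.null(j$variable_stats)) NULL else
      as.data.frame(j$variable_stats),
    lambda = j$lambda)
  structure(m, class = "stepwise_lda")
}

# canonical binary labels: accepts 0/1, logical, or 2-level factor
as_binary <- function(y) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (is.logical(y)) y <- as.integer(y)
  y <- as.integer(y)
  if (any(is.na(y)) || !all(y %in% c(0L, 1L))) {
    stop("labels must be binary 0/1 (inhibitor = 1)")
  }
  y
}
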