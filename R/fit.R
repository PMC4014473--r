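# REML log-likelihood (constant terms dropped)
reml_loglik <- function(y, X, V) {
  cv <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(cv)) return(-Inf)
  Vi <- chol2inv(cv)
  XtViX <- crossprod(X, Vi %*% X)
  cx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(cx)) return(-Inf)
  ViX <- Vi %*% X
  P <- Vi - ViX %*% chol2inv(cx) %*% t(ViX)
  -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
            drop(crossprod(y, P %*% y)))
}

# P matrix and derived pieces for a given set of variance components
mixed_model_pieces <- function(y, X, Gs, theta) {
  n <- length(y)
  V <- diag(theta[length(theta)], n)
  for (v in seq_along(Gs)) V <- V + theta[v] * Gs[[v]]
  cv <- chol(V)
  Vi <- chol2inv(cv)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  cx <- tryCatch(chol(XtViX), error = function(e) abort("singular fixed-effect block"))
  XtViX_inv <- chol2inv(cx)
  P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  Py <- drop(P %*% y)
  b <- drop(XtViX_inv %*% crossprod(ViX, y))
  ll <- -0.5 * (2 * sum(log(diag(cv))) + 2 * sum(log(diag(cx))) +
                  sum(y * Py))
  list(P = P, Py = Py, b = b, XtViX_inv = XtViX_inv, loglik = ll)
}

# Average-information REML with EM warm-up/fallback and truncate-and-refit
# handling of boundary components. Gs: list of U_v U_v' matrices; returns
# per-coefficient variance components (theta) for the groups plus residual.
reml_engine <- function(y, X, Gs, tol = 1e-6, max_iter = 200) {
  n <- length(y)
  k <- length(Gs)
  vary <- var(y)
  lb <- 1e-10 * vary
  qv <- c(vapply(seq_len(k), function(v) attr(Gs[[v]], "ncolU"), 1), n)
  theta <- rep(vary / (k + 1), k + 1)
  active <- rep(TRUE, k + 1)
  iter_total <- 0L

  eval_pieces <- function(theta) mixed_model_pieces(y, X, Gs, theta)

  repeat {
    pieces <- eval_pieces(theta)
    converged <- FALSE
    for (iter in seq_len(max_iter)) {
      iter_total <- iter_total + 1L
      idx <- which(active)
      # gradient building blocks; the residual group has G = I
      GPy <- lapply(idx, function(v) {
        if (v <= k) drop(Gs[[v]] %*% pieces$Py) else pieces$Py
      })
      trPG <- vapply(idx, function(v) {
        if (v <= k) sum(pieces$P * Gs[[v]]) else sum(diag(pieces$P))
      }, 1)
      yPGPy <- vapply(seq_along(idx), function(a) sum(pieces$Py * GPy[[a]]), 1)
      score <- -0.5 * (trPG - yPGPy)
      W <- vapply(GPy, identity, numeric(n))
      AI <- 0.5 * crossprod(W, pieces$P %*% W)

      step <- tryCatch(solve(AI, score), error = function(e) NULL)
      use_em <- iter <= 3L || is.null(step) || any(!is.finite(step))
      accepted <- FALSE
      if (!use_em) {
        halve <- 1
        for (try in 1:8) {
          cand <- theta
          cand[idx] <- pmax(theta[idx] + halve * step, lb)
          new_pieces <- tryCatch(eval_pieces(cand), error = function(e) NULL)
          if (!is.null(new_pieces) && new_pieces$loglik >= pieces$loglik - 1e-10) {
            accepted <- TRUE
            break
          }
          halve <- halve / 2
        }
      }
      if (!accepted) {
        # EM update: guaranteed ascent, slow near the boundary (where the
        # offending component gets truncated anyway)
        cand <- theta
        cand[idx] <- pmax(theta[idx] + theta[idx]^2 * (yPGPy - trPG) / qv[idx], lb)
        new_pieces <- eval_pieces(cand)
      }
      delta <- max(abs(cand - theta))
      theta <- cand
      pieces <- new_pieces
      if (delta < tol * vary) { converged <- TRUE; break }
    }
    if (!converged) {
      abort(message = "REML did not converge within `max_iter` iterations",
            class = "qtsmap_no_convergence", theta = theta)
    }
    # truncate boundary components to exactly zero and refit without them
    newly <- which(active & theta <= 10 * lb & seq_along(theta) <= k)
    if (!length(newly)) break
    theta[newly] <- 0
    active[newly] <- FALSE
  }
  list(theta = theta, pieces = pieces, iterations = iter_total,
       converged = TRUE)
}

# MINQUE(1): one-shot quadratic unbiased estimation with all prior values 1
minque1_engine <- function(y, X, Gs) {
  n <- length(y)
  k <- length(Gs)
  V0 <- diag(1, n)
  for (g in Gs) V0 <- V0 + g
  Vi <- chol2inv(chol(V0))
  ViX <- Vi %*% X
  XtViX_inv <- chol2inv(chol(crossprod(X, ViX)))
  Q <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  Qy <- drop(Q %*% y)
  Glist <- c(Gs, list(diag(1, n)))
  QG <- lapply(Glist, function(g) Q %*% g)
  S <- matrix(0, k + 1, k + 1)
  for (u in seq_len(k + 1)) for (v in u:(k + 1)) {
    S[u, v] <- S[v, u] <- sum(QG[[u]] * t(QG[[v]]))
  }
  qvec <- vapply(Glist, function(g) drop(crossprod(Qy, g %*% Qy)), 1)
  theta <- tryCatch(solve(S, qvec), error = function(e) abort("MINQUE system is singular"))
  pmax(theta, 0)
}

#' Fit the final mixed model on a selected term set
#'
#' Estimates one variance component per random-effect group (`A`, `AA`,
#' `AE`, `AAE`) plus the residual, predicts every random locus effect by
#' BLUP given the estimated components, and attaches a Wald-type
#' significance (-log10 p from predictor / standard error) to each
#' prediction. Negative component estimates are truncated to zero and the
#' model refit without them. Estimation is REML (average-information with
#' EM warm-up and fallback) or MINQUE(1).
#'
#' @param design An `assembled_design` from [build_design()].
#' @param method `"reml"` (default) or `"minque1"`.
#' @param tol Relative convergence tolerance on the variance components.
#' @param max_iter Maximum REML iterations.
#' @return A `qts_fit` object: `vc` (phenotypic variance components `V_A`,
#'   `V_AA`, `V_AE`, `V_AAE`, `V_e` and their sum `V_P`), `sigma2`
#'   (per-coefficient components), `effects` (tibble of predicted effects
#'   with `std_error` and `neg_log10_p`), `fixed` (grand mean and
#'   environment effects), convergence info.
#' @export
fit_mixed_model <- function(design, method = c("reml", "minque1"),
                            tol = 1e-6, max_iter = 200) {
  method <- match.arg(method)
  stopifnot(inherits(design, "assembled_design"))
  y <- design$y; X <- design$X
  U <- design$U[vapply(design$U, ncol, 1L) > 0]
  if (length(y) <= ncol(X)) abort("more fixed-effect columns than observations")
  groups <- names(U)
  Gs <- lapply(U, function(u) {
    g <- tcrossprod(u)
    attr(g, "ncolU") <- ncol(u)
    g
  })

  if (method == "reml") {
    eng <- reml_engine(y, X, Gs, tol = tol, max_iter = max_iter)
    theta <- eng$theta
    iterations <- eng$iterations
  } else {
    theta <- minque1_engine(y, X, Gs)
    iterations <- 1L
  }
  names(theta) <- c(groups, "resid")
  pieces <- mixed_model_pieces(y, X, Gs, theta)

  # BLUP predictions and Wald tests per random coefficient
  empty_effects <- tibble(group = character(), term = character(),
                          env = character(), column = character(),
                          effect = numeric(), std_error = numeric(),
                          neg_log10_p = numeric())
  effects <- purrr::map_dfr(seq_along(groups), function(v) {
    g <- groups[v]
    u_mat <- U[[g]]
    if (theta[v] > 0) {
      pred <- unname(theta[[v]] * drop(crossprod(u_mat, pieces$Py)))
      se <- unname(sqrt(pmax(diag(theta[[v]]^2 * crossprod(u_mat, pieces$P %*% u_mat)), 0)))
      z <- ifelse(se > 0, pred / se, 0)
      nlp <- -(pnorm(abs(z), lower.tail = FALSE, log.p = TRUE) + log(2)) / log(10)
    } else {
      pred <- se <- nlp <- rep(0, ncol(u_mat))
    }
    info <- design$col_info[design$col_info$group == g, ]
    tibble(group = g, term = info$term, env = info$env, column = info$column,
           effect = pred, std_error = se, neg_log10_p = pmax(nlp, 0))
  })
  if (!nrow(effects)) effects <- empty_effects

  envs <- design$envs
  b <- pieces$b
  fixed <- if (length(envs) > 1L) {
    eh <- c(b[-1], -sum(b[-1]))
    tibble(parameter = c("mu", paste0("e@", envs)), estimate = c(b[1], eh))
  } else {
    tibble(parameter = "mu", estimate = b[1])
  }

  col_var <- design$col_info
  vsum <- function(g) {
    if (!g %in% groups) return(0)
    unname(theta[g]) * sum(col_var$variance[col_var$group == g])
  }
  vc <- c(V_A = vsum("A"), V_AA = vsum("AA"), V_AE = vsum("AE"),
          V_AAE = vsum("AAE"), V_e = unname(theta["resid"]))
  vc <- c(vc, V_P = sum(vc))

  structure(list(method = method, converged = TRUE, iterations = iterations,
                 sigma2 = theta, vc = vc, effects = effects, fixed = fixed,
                 col_info = design$col_info, envs = envs,
                 trait = design$trait %||% NA_character_, n_obs = length(y),
                 loglik = pieces$loglik, terms = design$terms),
            class = "qts_fit")
}

#' @export
print.qts_fit <- function(x, ...) {
  cat(sprintf("<qts_fit> %s fit of trait '%s' (%d obs, %d random effects)\n",
              toupper(x$method), x$trait, x$n_obs, nrow(x$effects)))
  vc <- x$vc
  cat(sprintf("  components: V_A=%.4g V_AA=%.4g V_AE=%.4g V_AAE=%.4g V_e=%.4g (V_P=%.4g)\n",
              vc["V_A"], vc["V_AA"], vc["V_AE"], vc["V_AAE"], vc["V_e"], vc["V_P"]))
  invisible(x)
}

#' @describeIn fit_mixed_model Tidy the predicted effects.
#' @param x A `qts_fit`.
#' @param ... Unused.
#' @export
tidy.qts_fit <- function(x, ...) x$effects

#' @describeIn fit_mixed_model One-row model summary with variance
#'   components and total heritability.
#' @export
glance.qts_fit <- function(x, ...) {
  vc <- x$vc
  tibble(method = x$method, n_obs = x$n_obs, converged = x$converged,
         iterations = x$iterations, V_A = vc[["V_A"]], V_AA = vc[["V_AA"]],
         V_AE = vc[["V_AE"]], V_AAE = vc[["V_AAE"]], V_e = vc[["V_e"]],
         V_P = vc[["V_P"]],
         h2_total = 100 * (vc[["V_P"]] - vc[["V_e"]]) / vc[["V_P"]],
         logLik = x$loglik)
}

#' Refit a reduced model
#'
#' Refits the assembled design with interaction groups removed:
#' `"additive_only"` keeps only the `A` group, `"additive_plus_ae"` keeps
#' `A` and `AE`, `"full"` keeps everything. Mirrors full-versus-reduced
#' comparisons of total heritability.
#'
#' @param design An `assembled_design`.
#' @param model `"additive_only"`, `"additive_plus_ae"` or `"full"`.
#' @inheritParams fit_mixed_model
#' @return A `qts_fit` of the reduced model.
#' @export
refit_reduced <- function(design, model = c("full", "additive_only", "additive_plus_ae"),
                          method = c("reml", "minque1"), tol = 1e-6, max_iter = 200) {
  model <- match.arg(model)
  keep <- switch(model, full = c("A", "AA", "AE", "AAE"),
                 additive_only = "A", additive_plus_ae = c("A", "AE"))
  red <- design
  red$U <- design$U[intersect(names(design$U), keep)]
  red$col_info <- design$col_info[design$col_info$group %in% keep, ]
  fit_mixed_model(red, method = method, tol = tol, max_iter = max_iter)
}
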