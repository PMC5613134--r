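#' Define a random term of a multi-kernel mixed model
#'
#' A term is a Gaussian random effect `u ~ N(0, sigma2 * K)` over a set of
#' levels (parents, or hybrid crosses), attached to observations through a
#' data column holding the level id. The kinship may cover levels with no
#' observations: their BLUPs are then predicted through the kinship
#' covariance with observed levels, which is what makes untested parents
#' predictable.
#'
#' @param name term label (e.g. `"female"`).
#' @param column name of the data column carrying the level id.
#' @param kinship `kinship_matrix` (or plain symmetric matrix with dimnames)
#'   over all levels; `NULL` for an identity kinship (independent levels).
#' @param levels level ids for the identity case; required when
#'   `kinship = NULL` and prediction of unobserved levels is wanted.
#' @return object of class `random_term`.
#' @export
random_term <- function(name, column, kinship = NULL, levels = NULL) {
  if (is.null(kinship)) {
    assert_that(!is.null(levels), "identity term needs explicit levels")
    kinship <- diag(length(levels))
    dimnames(kinship) <- list(levels, levels)
    kinship <- new_kinship(kinship, "identity")
  }
  assert_that(!is.null(rownames(kinship)), "kinship needs level names")
  structure(list(name = name, column = column, kinship = kinship),
            class = "random_term")
}

# restricted log-likelihood and derivatives at one point of variance space.
# G: list of n x n observation-level covariance structures; X fixed design.
reml_eval <- function(y, X, G, sigma2, want_deriv = TRUE) {
  n <- length(y)
  p <- ncol(X)
  K <- length(G)
  V <- diag(sigma2[K + 1], n)
  for (k in seq_len(K)) V <- V + sigma2[k] * G[[k]]
  ch <- tryCatch(chol(V), error = function(e) NULL)
  if (is.null(ch)) return(NULL)
  logdetV <- 2 * sum(log(diag(ch)))
  Vi <- chol2inv(ch)
  ViX <- Vi %*% X
  XtViX <- crossprod(X, ViX)
  chx <- tryCatch(chol(XtViX), error = function(e) NULL)
  if (is.null(chx)) return(NULL)
  logdetX <- 2 * sum(log(diag(chx)))
  XtViX_inv <- chol2inv(chx)
  P <- Vi - ViX %*% XtViX_inv %*% t(ViX)
  Py <- P %*% y
  yPy <- drop(crossprod(y, Py))
  ll <- -0.5 * (logdetV + logdetX + yPy + (n - p) * log(2 * pi))
  out <- list(loglik = ll, P = P, Py = Py, Vi = Vi,
              XtViX_inv = XtViX_inv, ViX = ViX)
  if (want_deriv) {
    Gall <- c(G, list(NULL))  # NULL = identity (residual)
    GPy <- vector("list", K + 1)
    score <- numeric(K + 1)
    for (j in seq_len(K + 1)) {
      GPy[[j]] <- if (j <= K) G[[j]] %*% Py else Py
      trPG <- if (j <= K) sum(P * G[[j]]) else sum(diag(P))
      score[j] <- -0.5 * (trPG - drop(crossprod(Py, GPy[[j]])))
    }
    PGPy <- lapply(GPy, function(g) P %*% g)
    AI <- matrix(0, K + 1, K + 1)
    for (j in seq_len(K + 1)) for (l in j:(K + 1)) {
      AI[j, l] <- AI[l, j] <- 0.5 * drop(crossprod(GPy[[j]], PGPy[[l]]))
    }
    out$score <- score
    out$AI <- AI
  }
  out
}

#' Fit a multi-kernel linear mixed model by REML
#'
#' Maximizes the restricted log-likelihood of
#' `y = X b + sum_k Z_k u_k + e`, `u_k ~ N(0, sigma2_k K_k)`,
#' `e ~ N(0, sigma2_e I)` over the variance components, using
#' average-information Newton steps on log variances with step halving, then
#' reports variance components, their average-information standard errors,
#' the intercept (or fixed-effect) estimates and the BLUPs of every level of
#' every term — including levels with no observations, predicted through the
#' kinship. Components that converge to the lower floor
#' (`1e-10 x var(y)`) are reported as exactly 0 with a boundary flag.
#'
#' @param data data frame, one row per observation, containing the response
#'   and each term's level-id column.
#' @param terms list of [random_term()]s.
#' @param response name of the response column (default `"value"`).
#' @param fixed optional fixed-effect model formula (default intercept only);
#'   aliased columns are dropped.
#' @param max_iter maximum Newton iterations.
#' @param tol_loglik,tol_sigma convergence tolerances on the change of the
#'   restricted log-likelihood and the relative change of components.
#' @return object of class `hybridgs_fit`.
#' @export
reml_fit <- function(data, terms, response = "value", fixed = NULL,
                     max_iter = 200L, tol_loglik = 1e-8, tol_sigma = 1e-6) {
  data <- as.data.frame(data)
  y <- data[[response]]
  assert_that(is.numeric(y) && !anyNA(y), "response must be numeric, no NAs")
  n <- length(y)
  if (is.null(fixed)) {
    X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    X <- stats::model.matrix(fixed, data)
    qrX <- qr(X)
    if (qrX$rank < ncol(X)) X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  }
  K <- length(terms)
  assert_that(K >= 1, "at least one random term required")
  assert_that(n >= ncol(X) + 2, "too few observations for REML")

  idx <- vector("list", K)   # observation -> row of kinship
  G <- vector("list", K)
  for (k in seq_len(K)) {
    tk <- terms[[k]]
    lev <- data[[tk$column]]
    pos <- match(as.character(lev), rownames(tk$kinship))
    if (anyNA(pos))
      stop(sprintf("term '%s': level '%s' absent from its kinship",
                   tk$name, as.character(lev)[which(is.na(pos))[1]]),
           call. = FALSE)
    validate_kinship(tk$kinship)
    idx[[k]] <- pos
    G[[k]] <- unclass(tk$kinship)[pos, pos, drop = FALSE]
  }

  vy <- stats::var(y)
  if (vy <= 0) stop("response has zero variance", call. = FALSE)
  floor_s2 <- 1e-10 * vy
  gmean <- vapply(G, function(g) mean(diag(g)), 0)
  sigma2 <- c(vy / ((K + 1) * pmax(gmean, 1e-12)), vy / (K + 1))

  ev <- reml_eval(y, X, G, sigma2)
  if (is.null(ev)) stop("REML: singular covariance at start", call. = FALSE)
  trace <- data.frame(iter = 0L, loglik = ev$loglik)
  converged <- FALSE
  flat <- 0L
  slow <- 0L
  ai_cap <- min(max_iter, 30L)
  for (it in seq_len(ai_cap)) {
    theta <- log(sigma2)
    D <- diag(sigma2, K + 1)
    score_t <- sigma2 * ev$score
    AI_t <- D %*% ev$AI %*% D
    free <- !(sigma2 <= floor_s2 * 1.01 & score_t < 0)  # pinned & pushing down
    if (!any(free)) break
    step <- numeric(K + 1)
    Af <- AI_t[free, free, drop = FALSE]
    Af <- Af + diag(1e-8 * max(diag(Af), 1e-12), sum(free))
    step[free] <- tryCatch(solve(Af, score_t[free]),
                           error = function(e) score_t[free])
    step <- pmin(pmax(step, -4), 4)  # trust region on log scale
    try_direction <- function(step) {
      for (h in 0:12) {
        new_theta <- theta + step / 2^h
        new_s2 <- pmax(exp(new_theta), floor_s2)
        ev_new <- reml_eval(y, X, G, new_s2)
        if (!is.null(ev_new) && is.finite(ev_new$loglik) &&
            ev_new$loglik >= ev$loglik - 1e-12)
          return(list(s2 = new_s2, ev = ev_new))
      }
      NULL
    }
    cand <- try_direction(step)
    if (is.null(cand)) break  # Newton stalled: hand over to the polish
    ev_new <- cand$ev
    new_s2 <- cand$s2
    delta_ll <- ev_new$loglik - ev$loglik
    # components far below phenotypic scale are measured absolutely: a
    # near-boundary component drifting on the log scale must not stall
    # convergence when the likelihood is flat
    rel_ds2 <- max(abs(new_s2 - sigma2) /
                     pmax(pmax(sigma2, new_s2), 1e-4 * vy))
    sigma2 <- new_s2
    ev <- ev_new
    trace <- rbind(trace, data.frame(iter = it, loglik = ev$loglik))
    flat <- if (delta_ll < tol_loglik) flat + 1L else 0L
    slow <- if (delta_ll < 1e-6) slow + 1L else 0L
    # log-scale gradient at the new point; tiny for floored components
    grad_now <- max(abs(sigma2 * ev$score))
    if ((delta_ll < tol_loglik && rel_ds2 < tol_sigma) ||
        (flat >= 4L && grad_now < 1e-2)) {
      converged <- TRUE
      break
    }
    if (slow >= 10L) break  # crawling along a ridge: hand over to the polish
  }
  if (!converged) {
    # ridge in variance space (e.g. a weakly identified interaction vs
    # residual split): polish with bounded quasi-Newton on log variances
    cache <- new.env()
    evaluate <- function(theta) {
      key <- paste(signif(theta, 12), collapse = ",")
      if (!identical(cache$key, key)) {
        cache$key <- key
        cache$ev <- reml_eval(y, X, G, pmax(exp(theta), floor_s2),
                              want_deriv = TRUE)
      }
      cache$ev
    }
    fn <- function(theta) {
      e <- evaluate(theta)
      if (is.null(e) || !is.finite(e$loglik)) return(1e10)
      -e$loglik
    }
    gr <- function(theta) {
      e <- evaluate(theta)
      if (is.null(e)) return(rep(0, length(theta)))
      -pmax(exp(theta), floor_s2) * e$score
    }
    opt <- tryCatch(
      stats::optim(log(pmax(sigma2, floor_s2)), fn, gr, method = "L-BFGS-B",
                   lower = log(floor_s2), upper = log(1e6 * vy / pmin(c(gmean, 1), 1)),
                   control = list(maxit = 100, factr = 1e4)),
      error = function(e) NULL)
    if (!is.null(opt) && -opt$value >= ev$loglik - 1e-8) {
      sigma2 <- pmax(exp(opt$par), floor_s2)
      ev2 <- reml_eval(y, X, G, sigma2)
      if (!is.null(ev2)) ev <- ev2
      converged <- TRUE
      trace <- rbind(trace, data.frame(iter = max(trace$iter) + 1L,
                                       loglik = ev$loglik))
    } else {
      stop("REML did not converge; trace:\n",
           paste(utils::capture.output(utils::tail(trace)), collapse = "\n"),
           call. = FALSE)
    }
  }

  # anything this far below phenotypic scale is a boundary zero (printed 0)
  boundary <- sigma2 <= 1e-6 * vy
  sigma2_rep <- ifelse(boundary, 0, sigma2)
  names(sigma2_rep) <- c(vapply(terms, `[[`, "", "name"), "residual")
  names(boundary) <- names(sigma2_rep)

  beta <- drop(ev$XtViX_inv %*% crossprod(X, ev$Vi %*% y))
  names(beta) <- colnames(X)

  # BLUPs over every kinship level: u_k = sigma2_k K_k Z_k' P y
  blup <- vector("list", K)
  names(blup) <- names(sigma2_rep)[seq_len(K)]
  for (k in seq_len(K)) {
    Kmat <- unclass(terms[[k]]$kinship)
    agg <- numeric(nrow(Kmat))
    tt <- tapply(ev$Py, idx[[k]], sum)
    agg[as.integer(names(tt))] <- tt
    u <- sigma2_rep[k] * drop(Kmat %*% agg)
    names(u) <- rownames(Kmat)
    blup[[k]] <- u
  }

  se <- rep(NA_real_, K + 1)
  AIi <- tryCatch(solve(ev$AI), error = function(e) NULL)
  if (!is.null(AIi)) se <- sqrt(pmax(diag(AIi), 0))
  names(se) <- names(sigma2_rep)

  structure(list(
    mu = unname(beta[1]), beta = beta, sigma2 = sigma2_rep, se = se,
    boundary = boundary, blup = blup, loglik = ev$loglik, ai = ev$AI,
    terms = terms, n = n, n_iter = max(trace$iter), converged = TRUE,
    trace = trace, response = response
  ), class = "hybridgs_fit")
}

#' @export
print.hybridgs_fit <- function(x, ...) {
  cat(sprintf("<hybridgs_fit> n = %d, restricted logLik = %.4f (%d iter)\n",
              x$n, x$loglik, x$n_iter))
  print(tidy.hybridgs_fit(x))
  invisible(x)
}

#' Tidy variance components of a fitted model
#'
#' @param x a `hybridgs_fit`.
#' @param ... unused.
#' @return tibble with `term`, `variance`, `std_error`, `z_ratio` (NA at the
#'   boundary), `share` (part of variance) and `boundary`.
#' @method tidy hybridgs_fit
#' @export
tidy.hybridgs_fit <- function(x, ...) {
  shares <- x$sigma2 / sum(x$sigma2)
  tibble::tibble(
    term = names(x$sigma2),
    variance = unname(x$sigma2),
    std_error = unname(x$se),
    z_ratio = ifelse(x$boundary, NA_real_, x$sigma2 / x$se),
    share = unname(shares),
    boundary = unname(x$boundary))
}

#' One-line model summary
#' @param x a `hybridgs_fit`.
#' @param ... unused.
#' @return tibble with `n`, `logLik`, `n_terms`, `n_iter`, `converged`.
#' @method glance hybridgs_fit
#' @export
glance.hybridgs_fit <- function(x, ...) {
  tibble::tibble(n = x$n, logLik = x$loglik, n_terms = length(x$terms),
                 n_iter = x$n_iter, converged = x$converged)
}
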