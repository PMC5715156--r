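# Closed-population abundance estimation by conditional (Huggins-type)
# likelihood: constant, time-varying, sex-covariate and two-class finite
# mixture detection models, with BIC model selection and per-year series.

logit <- function(p) log(p / (1 - p))
expit <- function(x) 1 / (1 + exp(-x))
LOGIT_CAP <- 12  # keeps p in (6e-6, 1 - 6e-6); boundary fits are flagged

# Negative conditional log-likelihood functions. `m` is the n x k detection
# matrix; each individual's contribution is P(history) / P(detected >= once).
closed_negloglik <- function(model, m, sex = NULL) {
  n <- nrow(m); k <- ncol(m)
  y <- rowSums(m)
  switch(model,
    M0 = function(th) {
      p <- expit(th[1L])
      pd <- 1 - (1 - p)^k
      -(sum(y) * log(p) + (n * k - sum(y)) * log(1 - p) - n * log(pd))
    },
    Mt = function(th) {
      p <- expit(th)
      mj <- colSums(m)
      pd <- 1 - prod(1 - p)
      -(sum(mj * log(p) + (n - mj) * log(1 - p)) - n * log(pd))
    },
    Msex = function(th) {
      p <- expit(th[1L] + th[2L] * (sex == "M"))
      pd <- 1 - (1 - p)^k
      -sum(y * log(p) + (k - y) * log(1 - p) - log(pd))
    },
    Mh2 = function(th) {
      p1 <- expit(th[1L]); p2 <- expit(th[2L]); pi1 <- expit(th[3L])
      lik <- pi1 * p1^y * (1 - p1)^(k - y) +
        (1 - pi1) * p2^y * (1 - p2)^(k - y)
      pd <- 1 - (pi1 * (1 - p1)^k + (1 - pi1) * (1 - p2)^k)
      -(sum(log(lik)) - n * log(pd))
    },
    stop("unknown model ", model))
}

# P(detected at least once) per individual at parameters th.
closed_pdetect <- function(model, th, m, sex = NULL) {
  n <- nrow(m); k <- ncol(m)
  switch(model,
    M0 = rep(1 - (1 - expit(th[1L]))^k, n),
    Mt = rep(1 - prod(1 - expit(th)), n),
    Msex = {
      p <- expit(th[1L] + th[2L] * (sex == "M"))
      1 - (1 - p)^k
    },
    Mh2 = {
      p1 <- expit(th[1L]); p2 <- expit(th[2L]); pi1 <- expit(th[3L])
      rep(1 - (pi1 * (1 - p1)^k + (1 - pi1) * (1 - p2)^k), n)
    })
}

#' Fit a closed-population model by conditional likelihood
#'
#' Maximises the Huggins-type conditional likelihood (each observed
#' individual's history probability conditioned on being detected at least
#' once) over detection parameters on the logit scale, then recovers
#' abundance by the Horvitz-Thompson sum `N_hat = sum_i 1 / P(detected_i)`.
#' The standard error combines the conditional-likelihood binomial component
#' `sum (1 - pi) / pi^2` with the delta-method parameter-uncertainty term.
#'
#' Models: `M0` constant detection; `Mt` per-occasion detection; `Msex`
#' logit-linear sex effect (needs `sex`); `Mh2` two-class finite mixture
#' with weight `pi1`, fitted from multiple random starts (classes ordered
#' `p1 < p2`).
#'
#' @param m binary detection matrix, individuals x secondary occasions
#'   (at least 2 occasions), e.g. from [year_matrix()] of a
#'   `capture_histories` object.
#' @param model one of `"M0"`, `"Mt"`, `"Msex"`, `"Mh2"`.
#' @param sex per-individual `"F"`/`"M"` labels (Msex only).
#' @param n_starts random starts for `Mh2`.
#' @param seed seed for the random starts.
#' @return Object of class `closed_pop_fit`: `model`, `N_hat`, `se_N`,
#'   `params` (natural scale), `loglik`, `n_observed`, `k_occasions`,
#'   `n_params`, `BIC`, `converged` (FALSE flags a boundary /
#'   non-identifiable fit, with `N_hat` suppressed to `NA`).
#' @export
fit_closed <- function(m, model = c("M0", "Mt", "Msex", "Mh2"), sex = NULL,
                       n_starts = 5L, seed = 1L) {
  model <- match.arg(model)
  m <- as.matrix(m); storage.mode(m) <- "integer"
  n <- nrow(m); k <- ncol(m)
  if (k < 2L) stop("need at least 2 secondary occasions")
  if (n < 1L) stop("need at least one observed individual")
  if (any(rowSums(m) == 0L)) stop("matrix contains an all-zero history")
  if (model == "Msex") {
    if (is.null(sex) || length(sex) != n || !all(sex %in% c("F", "M"))) {
      stop("Msex needs a valid sex label per individual")
    }
  }
  nll <- closed_negloglik(model, m, sex)
  npar <- switch(model, M0 = 1L, Mt = k, Msex = 2L, Mh2 = 3L)

  p0 <- logit(min(max(mean(m), 0.05), 0.95))
  starts <- switch(model,
    M0 = list(p0),
    Mt = list(rep(p0, k)),
    Msex = list(c(p0, 0)),
    Mh2 = with_seed(seed, lapply(seq_len(max(2L, n_starts)), function(i) {
      c(p0 + stats::rnorm(1, -1, 1), p0 + stats::rnorm(1, 1, 1),
        stats::rnorm(1, 0, 1))
    })))

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, nll, method = "L-BFGS-B",
                   lower = rep(-LOGIT_CAP, npar), upper = rep(LOGIT_CAP, npar),
                   control = list(factr = 10)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value - 1e-9) best <- fit
  }
  if (is.null(best)) stop("optimisation failed for model ", model)
  th <- best$par
  if (model == "Mh2" && expit(th[1L]) > expit(th[2L])) {
    th <- c(th[2L], th[1L], logit(1 - expit(th[3L])))  # canonical p1 < p2
  }
  pdet <- closed_pdetect(model, th, m, sex)
  N_hat <- sum(1 / pdet)

  # boundary detection probabilities (p -> 0) make N unidentifiable
  ps <- switch(model,
    M0 = expit(th[1L]), Mt = expit(th), Mh2 = expit(th[1:2]),
    Msex = expit(th[1L] + th[2L] * c(0, 1)))
  boundary_low <- any(ps < 1e-4) || any(pdet < 1e-4)

  # variance: binomial component + delta-method term from the information
  se_N <- tryCatch({
    H <- stats::optimHess(th, nll)
    V <- solve(H)
    eps <- 1e-5
    grad <- vapply(seq_len(npar), function(j) {
      tp <- th; tm <- th
      tp[j] <- tp[j] + eps; tm[j] <- tm[j] - eps
      (sum(1 / closed_pdetect(model, tp, m, sex)) -
         sum(1 / closed_pdetect(model, tm, m, sex))) / (2 * eps)
    }, numeric(1))
    v <- sum((1 - pdet) / pdet^2) + drop(t(grad) %*% V %*% grad)
    # a near-singular information matrix (flat mixture likelihood) can push
    # the delta-method variance negative; report the SE as unavailable
    if (!is.finite(v) || v < 0) NA_real_ else sqrt(v)
  }, error = function(e) NA_real_)

  params <- switch(model,
    M0 = c(p = expit(th[1L])),
    Mt = stats::setNames(expit(th), paste0("p", seq_len(k))),
    Msex = c(p_F = expit(th[1L]), p_M = expit(th[1L] + th[2L])),
    Mh2 = c(p1 = expit(th[1L]), p2 = expit(th[2L]), pi1 = expit(th[3L])))

  out <- list(model = model,
              N_hat = if (boundary_low) NA_real_ else N_hat,
              se_N = if (boundary_low) NA_real_ else se_N,
              params = params, loglik = -best$value,
              n_observed = n, k_occasions = k, n_params = npar,
              BIC = 2 * best$value + npar * log(n),
              converged = !boundary_low)
  class(out) <- "closed_pop_fit"
  out
}

#' @export
print.closed_pop_fit <- function(x, ...) {
  cat(sprintf("%s fit: N_hat = %.1f (SE %.2f), n_observed = %d, BIC = %.2f\n",
              x$model, x$N_hat, x$se_N, x$n_observed, x$BIC))
  cat("  detection: ", paste(sprintf("%s = %.3f", names(x$params), x$params),
                             collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Select a closed-population model by BIC
#'
#' `BIC = -2 loglik + n_params * log(n_observed)`; ties (within 1e-9) are
#' broken toward the model with fewer parameters.
#'
#' @param fits list of [fit_closed()] results on the same data.
#' @return The minimum-BIC converged fit.
#' @export
select_model <- function(fits) {
  if (inherits(fits, "closed_pop_fit")) fits <- list(fits)
  fits <- Filter(function(f) isTRUE(f$converged), fits)
  if (!length(fits)) stop("no converged fits to select from")
  bic <- vapply(fits, `[[`, numeric(1), "BIC")
  np <- vapply(fits, `[[`, numeric(1), "n_params")
  fits[[order(round(bic, 9), np)[1L]]]
}

#' Lincoln-Petersen two-sample abundance estimator
#'
#' The classical closed-form estimate `N = n1 * n2 / m` from two occasions
#' (`n1`, `n2` marked per occasion, `m` recaptured on both).
#'
#' @param m binary detection matrix with exactly 2 columns.
#' @return The Lincoln-Petersen estimate.
#' @export
lincoln_petersen <- function(m) {
  m <- as.matrix(m)
  stopifnot(ncol(m) == 2L)
  n1 <- sum(m[, 1L]); n2 <- sum(m[, 2L]); recap <- sum(m[, 1L] & m[, 2L])
  if (recap == 0) stop("no recaptures: Lincoln-Petersen undefined")
  n1 * n2 / recap
}

#' Annual abundance series from capture histories
#'
#' Fits the candidate closed models independently within each primary year,
#' selects by BIC, and reports the per-year abundance estimates. Years with
#' fewer than 2 secondary occasions are skipped with a warning; translocated
#' individuals should be excluded via `exclude_ids`.
#'
#' @param ch a `capture_histories` object (see [read_capture_csv()]).
#' @param models candidate models; `"Msex"` is fitted only when `sex`
#'   provides a label for every individual in a year.
#' @param sex named `"F"`/`"M"` vector (names = individual ids), optional.
#' @param exclude_ids ids to drop (e.g. translocated animals).
#' @param seed seed for mixture starts.
#' @return Data frame `year`, `model`, `n_observed`, `N_hat`, `se_N`.
#' @export
annual_abundance_series <- function(ch, models = c("M0", "Mt", "Mh2"),
                                    sex = NULL, exclude_ids = NULL,
                                    seed = 1L) {
  if (!is.null(exclude_ids)) {
    ch <- validate_capture_histories(
      as.data.frame(ch)[!ch$id %in% exclude_ids, , drop = FALSE])
  }
  years <- sort(unique(ch$year))
  rows <- list()
  for (y in years) {
    m <- year_matrix(ch, y)
    if (ncol(m) < 2L || nrow(m) < 1L) {
      warning("year ", y, " skipped: fewer than 2 secondary occasions")
      next
    }
    sx <- if (!is.null(sex)) unname(sex[rownames(m)]) else NULL
    cands <- models
    if ("Msex" %in% cands && (is.null(sx) || anyNA(sx))) {
      cands <- setdiff(cands, "Msex")
    }
    fits <- lapply(cands, function(mod) {
      tryCatch(fit_closed(m, mod, sex = sx, seed = sub_seed(seed, y)),
               error = function(e) NULL)
    })
    fits <- Filter(Negate(is.null), fits)
    if (!length(fits)) next
    sel <- tryCatch(select_model(fits), error = function(e) NULL)
    if (is.null(sel)) next
    rows[[as.character(y)]] <- data.frame(
      year = y, model = sel$model, n_observed = sel$n_observed,
      N_hat = sel$N_hat, se_N = sel$se_N, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
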