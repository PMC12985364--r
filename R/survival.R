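#' Discretize survival times into quartile intervals
#'
#' Cut points are the empirical quartiles (linear-interpolation, type 7) of
#' the *uncensored* subjects' survival times; every subject — censored or not
#' — is labelled by the interval containing its observed time, with times
#' beyond the last cut assigned to the last interval. Labels are 0-based
#' (`0 .. n_intervals - 1`).
#'
#' @param times Observed times (> 0).
#' @param censor Censor flags (1 = survives beyond follow-up, 0 = event).
#' @param n_intervals Number of discrete intervals (default 4: quartiles).
#' @return List with `cuts` (the `n_intervals - 1` interior cut points),
#'   `breaks` (`c(0, cuts, Inf)`), `labels` (0-based interval per subject).
#' @export
discretize_times <- function(times, censor, n_intervals = 4L) {
  stop_if(length(times) != length(censor), "times and censor lengths differ")
  unc <- times[censor == 0]
  stop_if(length(unc) < n_intervals,
          "need at least n_intervals uncensored subjects")
  cuts <- unname(stats::quantile(unc, probs = seq_len(n_intervals - 1) / n_intervals,
                                 type = 7))
  stop_if(anyDuplicated(cuts) > 0,
          "degenerate cut points (tied quartiles); too little spread in times")
  labels <- findInterval(times, cuts) # [t_r, t_{r+1}) membership, 0-based
  list(cuts = cuts, breaks = c(0, cuts, Inf), labels = as.integer(labels))
}

#' Survival function from discrete hazards
#'
#' `S(0) = 1` (empty product) and `S(r) = prod_{u=1..r} (1 - h_u)`; the
#' result is non-increasing in r.
#'
#' @param hazards Vector of per-interval hazards, each in (0, 1) (0 and 1
#'   are tolerated at the boundaries of validity: hazards outside \[0, 1\]
#'   raise an error).
#' @return Numeric vector `S(0..R)` of length `length(hazards) + 1`.
#' @export
survival_from_hazard <- function(hazards) {
  stop_if(any(hazards < 0 | hazards > 1), "hazards must lie in [0, 1]")
  s <- c(1, cumprod(1 - hazards))
  names(s) <- paste0("S", seq_along(s) - 1)
  s
}

# clamp probabilities inside logs; warn when clamping actually occurs
log_clamped <- function(p, eps = 1e-7) {
  if (any(p < eps)) warning("probability clamped to ", eps, " inside log")
  log(pmax(p, eps))
}

#' Discrete-time survival loss for one subject
#'
#' The negative log-likelihood of the discrete hazard model,
#' `L = -c log S(Y) - (1-c) log S(Y-1) - (1-c) log h_Y`, combined with the
#' uncensored-only part `L_unc = -(1-c) (log S(Y-1) + log h_Y)` as the
#' weighted sum `L_surv = (1-beta) L + beta L_unc`. The 0-based interval
#' label maps to the 1-based hazard index `u = Y + 1`, so a censored subject
#' contributes `-log S(u)` (survival through its interval) and an uncensored
#' one `-log S(u-1) - log h_u`. Since `L == L_unc` for uncensored subjects,
#' beta effectively down-weights censored cases.
#'
#' @param hazards Per-interval hazards in (0, 1), length R.
#' @param label 0-based interval label Y.
#' @param censor 1 = censored (survives beyond follow-up), 0 = event.
#' @param beta Uncensored up-weighting in \[0, 1\] (default 0.5).
#' @return Scalar loss `L_surv`.
#' @export
survival_loss <- function(hazards, label, censor, beta = 0.5) {
  stop_if(beta < 0 || beta > 1, "beta must be in [0, 1]")
  stop_if(label < 0 || label >= length(hazards), "label out of range")
  s <- survival_from_hazard(hazards)
  u <- label + 1L
  if (censor == 1) {
    L <- -log_clamped(s[u + 1L]) # -log S(u)
    L_unc <- 0
  } else {
    L <- -log_clamped(s[u]) - log_clamped(hazards[u]) # -log S(u-1) - log h_u
    L_unc <- L
  }
  unname((1 - beta) * L + beta * L_unc)
}

#' Fit a linear discrete-time hazard model
#'
#' Hazard logits are `z_r = b_r + x' v` (per-interval intercepts, shared
#' slope); hazards are `sigmoid(z_r)`. The mean [survival_loss()] over the
#' cohort is minimized by full-batch Adam; the fit is deterministic under
#' `seed`. A shared slope keeps the model a proportional-odds-style risk
#' score whose weights are directly comparable with a generating linear
#' risk.
#'
#' @param cohort A `survival_cohort` (see [generate_survival_cohort()]).
#' @param n_intervals Number of discrete intervals (default 4).
#' @param beta Uncensored up-weighting (default 0.5).
#' @param epochs Gradient steps (default 300).
#' @param learning_rate Adam step size (default 0.1; 0 leaves parameters at
#'   their initial values).
#' @param seed Seed for initialization.
#' @return A `hazard_model`: `weights` (shared slope v), `intercepts`
#'   (per-interval b), `cuts`, `breaks`, `beta`, `trace` (loss per epoch).
#' @export
fit_hazard_model <- function(cohort, n_intervals = 4L, beta = 0.5,
                             epochs = 300L, learning_rate = 0.1, seed = 1L) {
  X <- cohort$features
  n <- nrow(X); p <- ncol(X)
  disc <- discretize_times(cohort$time, cohort$censor, n_intervals)
  u <- disc$labels + 1L # 1-based event/censor interval
  cvec <- cohort$censor
  # per-subject, per-interval contribution masks:
  #   censored:    -log(1-h_r) for r <= u      (survives through interval u)
  #   uncensored:  -log(1-h_r) for r <= u - 1, and -log h_u
  R <- n_intervals
  surv_mask <- outer(ifelse(cvec == 1, u, u - 1L), seq_len(R), ">=") * 1
  event_mask <- outer(u, seq_len(R), "==") * (cvec == 0)
  wt <- ifelse(cvec == 1, 1 - beta, 1) # L == L_unc for uncensored subjects
  with_seed(seed, {
    params <- list(v = stats::rnorm(p, sd = 0.01), b = numeric(R))
    st <- adam_state(params)
    trace <- numeric(epochs)
    for (ep in seq_len(epochs)) {
      z <- outer(as.vector(X %*% params$v), rep(1, R)) +
        matrix(params$b, n, R, byrow = TRUE)
      h <- stats::plogis(z)
      loss <- -sum(wt * (rowSums(surv_mask * log_clamped_mat(1 - h)) +
                           rowSums(event_mask * log_clamped_mat(h)))) / n
      trace[ep] <- loss
      if (!is.finite(loss)) {
        stop("hazard fit diverged (non-finite loss) at epoch ", ep,
             call. = FALSE)
      }
      # d loss / d z
      dz <- (surv_mask * h - event_mask * (1 - h)) * wt / n
      grads <- list(v = as.vector(crossprod(X, rowSums(dz))),
                    b = colSums(dz))
      up <- adam_step(params, grads, st, learning_rate)
      params <- up$params
      st <- up$state
    }
    structure(list(weights = params$v, intercepts = params$b,
                   cuts = disc$cuts, breaks = disc$breaks, beta = beta,
                   n_intervals = R, trace = trace),
              class = "hazard_model")
  })
}

log_clamped_mat <- function(p, eps = 1e-7) log(pmax(p, eps))

#' @export
print.hazard_model <- function(x, ...) {
  cat(sprintf("hazard_model: %d intervals, cuts at %s\n", x$n_intervals,
              paste(signif(x$cuts, 4), collapse = ", ")))
  invisible(x)
}

#' Predict from a hazard model
#'
#' @param object A `hazard_model`.
#' @param features n x p feature matrix.
#' @param type `"risk"` (the linear predictor `x'v`; higher = shorter
#'   survival), `"hazard"` (n x R hazard matrix) or `"survival"`
#'   (n x (R+1) survival curves S(0..R)).
#' @param ... Unused.
#' @return See `type`.
#' @export
predict.hazard_model <- function(object, features, type = c("risk", "hazard",
                                                            "survival"), ...) {
  type <- match.arg(type)
  features <- as.matrix(features)
  risk <- as.vector(features %*% object$weights)
  if (type == "risk") return(risk)
  z <- outer(risk, rep(1, object$n_intervals)) +
    matrix(object$intercepts, length(risk), object$n_intervals, byrow = TRUE)
  h <- stats::plogis(z)
  if (type == "hazard") return(h)
  t(apply(h, 1, survival_from_hazard))
}

#' Concordance index for censored survival data
#'
#' Fraction of admissible pairs whose predicted ordering matches the
#' observed survival-time ordering. `scores` are survival-time-like (higher
#' = longer predicted survival); negate a risk score before calling.
#' Admissible pairs are those where the earlier time is an observed event;
#' ties in score count 1/2 (Harrell's convention).
#'
#' @param scores Predicted survival-time surrogates.
#' @param times Observed times.
#' @param censor 1 = censored, 0 = event observed.
#' @return Scalar C-index in \[0, 1\].
#' @export
concordance_index <- function(scores, times, censor = rep(0, length(times))) {
  n <- length(times)
  stop_if(length(scores) != n || length(censor) != n, "length mismatch")
  # pair (i, j) admissible iff T_i < T_j and subject i had an observed event
  lt <- outer(times, times, "<")
  adm <- lt & (censor == 0)
  stop_if(!any(adm), "no admissible pairs")
  conc <- outer(scores, scores, "<")
  tied <- outer(scores, scores, "==")
  (sum(conc[adm]) + 0.5 * sum(tied[adm])) / sum(adm)
}

#' Pool spot-level values into a slide-level feature vector
#'
#' `average` takes column means; `attention` takes a softmax-weighted mean
#' with per-spot scores from a learned gating vector (zero gating gives
#' equal scores, i.e. the average).
#'
#' @param spot_values Spots x features matrix (e.g. predicted abundances).
#' @param mode `"average"` or `"attention"`.
#' @param gate Gating vector (length = n features) for attention pooling;
#'   defaults to zeros.
#' @return Length-features numeric vector.
#' @export
pool_slide <- function(spot_values, mode = c("average", "attention"),
                       gate = NULL) {
  mode <- match.arg(mode)
  m <- as.matrix(spot_values)
  stop_if(nrow(m) < 1, "empty slide")
  if (mode == "average") return(colMeans(m))
  if (is.null(gate)) gate <- numeric(ncol(m))
  s <- as.vector(m %*% gate)
  w <- exp(s - max(s))
  w <- w / sum(w)
  as.vector(crossprod(m, w))
}

#' Kaplan-Meier risk stratification
#'
#' Splits subjects into high- and low-risk groups at the median of the risk
#' scores (higher score = higher risk), fits the product-limit (Kaplan-Meier)
#' estimator per group, and reports a log-rank separation test.
#'
#' @param scores Risk scores (non-constant).
#' @param times Observed times.
#' @param censor 1 = censored, 0 = event.
#' @param split Split rule; only `"median"` is implemented.
#' @return List with `group` (factor high/low per subject), `curves`
#'   (data.frame `time`, `survival`, `group`), `logrank_chisq`, `p_value`.
#' @export
km_stratify <- function(scores, times, censor, split = "median") {
  stop_if(split != "median", "only median split is implemented")
  stop_if(stats::sd(scores) == 0, "constant scores cannot be stratified")
  grp <- factor(ifelse(scores > stats::median(scores), "high", "low"),
                levels = c("low", "high"))
  stop_if(min(table(grp)) < 2, "need at least 2 subjects per group")
  event <- 1 - censor
  fit <- survival::survfit(survival::Surv(times, event) ~ grp)
  strata_names <- rep(names(fit$strata) %||% "all", fit$strata %||% length(fit$time))
  curves <- data.frame(time = fit$time, survival = fit$surv,
                       group = sub("^grp=", "", strata_names),
                       stringsAsFactors = FALSE)
  if (sum(event) == 0) {
    # no events anywhere: the log-rank statistic is undefined
    return(list(group = grp, curves = curves, logrank_chisq = NA_real_,
                p_value = NA_real_))
  }
  lr <- survival::survdiff(survival::Surv(times, event) ~ grp)
  list(group = grp, curves = curves, logrank_chisq = lr$chisq,
       p_value = stats::pchisq(lr$chisq, df = 1, lower.tail = FALSE))
}

#' Integrated-gradients feature attribution
#'
#' Right-Riemann approximation of the path integral of gradients from a
#' baseline to the input:
#' `IG_k = (x_k - x0_k) * (1/steps) * sum_{s=1..steps} dF/dx_k |_{x0 + (s/steps)(x - x0)}`.
#' Satisfies completeness (`sum(IG) ~= F(x) - F(x0)`) up to the Riemann
#' error, and is exact for linear F at any step count.
#'
#' @param f Scalar-valued differentiable function of a feature vector.
#' @param x Input feature vector.
#' @param baseline Baseline vector (same length).
#' @param steps Number of Riemann steps (>= 2).
#' @param grad_fn Optional gradient function; central finite differences are
#'   used when absent.
#' @return Attribution vector, same length as `x`.
#' @export
integrated_gradients <- function(f, x, baseline, steps = 64L,
                                 grad_fn = NULL) {
  stop_if(length(x) != length(baseline), "baseline length mismatch")
  stop_if(steps < 2, "steps must be >= 2")
  if (is.null(grad_fn)) {
    grad_fn <- function(z, h = 1e-5) {
      vapply(seq_along(z), function(k) {
        zp <- z; zm <- z
        zp[k] <- zp[k] + h
        zm[k] <- zm[k] - h
        (f(zp) - f(zm)) / (2 * h)
      }, numeric(1))
    }
  }
  g <- numeric(length(x))
  for (s in seq_len(steps)) {
    g <- g + grad_fn(baseline + (s / steps) * (x - baseline))
  }
  (x - baseline) * g / steps
}

#' Cell-type attribution heatmap for a fitted hazard model
#'
#' Integrated gradients of each interval's hazard with respect to the
#' slide-level cell-type features, averaged over slides — the per-interval
#' attribution profile relating cell populations to short- versus long-term
#' mortality risk.
#'
#' @param model A `hazard_model`.
#' @param features n x p matrix of slide-level features.
#' @param baseline Baseline feature vector (default zeros).
#' @param steps Riemann steps.
#' @return R x p matrix: mean attribution of each feature per interval.
#' @export
hazard_attribution <- function(model, features, baseline = NULL,
                               steps = 64L) {
  features <- as.matrix(features)
  p <- ncol(features)
  if (is.null(baseline)) baseline <- numeric(p)
  R <- model$n_intervals
  out <- matrix(0, R, p, dimnames = list(paste0("interval_", seq_len(R) - 1),
                                         colnames(features)))
  for (r in seq_len(R)) {
    f_r <- function(z) {
      stats::plogis(model$intercepts[r] + sum(z * model$weights))
    }
    grad_r <- function(z) {
      h <- stats::plogis(model$intercepts[r] + sum(z * model$weights))
      h * (1 - h) * model$weights
    }
    acc <- numeric(p)
    for (i in seq_len(nrow(features))) {
      acc <- acc + integrated_gradients(f_r, features[i, ], baseline,
                                        steps = steps, grad_fn = grad_r)
    }
    out[r, ] <- acc / nrow(features)
  }
  out
}
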