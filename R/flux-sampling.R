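# Uniform sampling of the steady-state flux polytope {v : S v = 0,
# lb <= v <= ub} by hit-and-run in the null space of S, with artificial
# centering (directions drawn through the running sample mean), and the
# correlation analysis of sampled fluxes against the target reaction.

#' Sample steady-state flux distributions
#'
#' Draws approximately uniform flux vectors from the steady-state polytope
#' of a metabolic model using artificially-centered hit-and-run (ACHR).
#' The flux space is parameterized by an orthonormal basis of the null
#' space of the stoichiometric matrix, so every iterate satisfies
#' `S v = 0` to numerical precision by construction; the chord search
#' enforces the bounds. Warm-up directions are isotropic in the null
#' space; after `burn_in` steps directions run through the running sample
#' mean (the artificial centering), which adapts step geometry to
#' elongated polytopes. A degenerate polytope (a single feasible point,
#' e.g. a fully determined linear chain) is detected and returned as that
#' point replicated.
#'
#' @param model A [metabolic_model()].
#' @param n_samples Number of flux vectors to return (>= 2).
#' @param method Sampling algorithm; only `"achr"` is implemented.
#' @param seed Integer seed (sampling is fully reproducible).
#' @param tol Steady-state residual tolerance: every sample must satisfy
#'   `max |S v| <= tol`.
#' @param burn_in Warm-up iterations discarded before recording.
#' @param thin Record every `thin`-th iterate after warm-up.
#' @return Object of class `flux_samples`: list with `samples`
#'   (`n_samples` x `n_reactions` matrix, columns named by reaction id),
#'   `residuals` (per-sample `max |S v|`), `model`, `point_polytope`
#'   (logical), and the sampler settings.
#' @export
sample_fluxes <- function(model, n_samples = 1000, method = "achr",
                          seed = 1L, tol = 1e-8, burn_in = 500, thin = 25) {
  stopifnot(inherits(model, "metabolic_model"))
  if (!identical(method, "achr")) {
    stop("unknown sampling method '", method, "'", call. = FALSE)
  }
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  S <- model$S
  lb <- model$reactions$lb
  ub <- model$reactions$ub
  r <- ncol(S)
  # fold reactions with equal bounds into the equality system, so the
  # feasible set spans the full dimension of the sampled coordinate space
  # (a fixed uptake would otherwise make every random chord degenerate)
  fixed <- which(ub - lb <= 1e-12 * pmax(1, abs(lb)))
  A <- S
  b <- rep(0, nrow(S))
  if (length(fixed)) {
    E <- matrix(0, length(fixed), r)
    E[cbind(seq_along(fixed), fixed)] <- 1
    A <- rbind(S, E)
    b <- c(b, lb[fixed])
  }
  v_p <- qr.coef(qr(A), b)
  v_p[is.na(v_p)] <- 0
  if (max(abs(A %*% v_p - b)) > 1e-8) {
    stop("model is infeasible: the fixed-flux constraints are ",
         "inconsistent with steady state", call. = FALSE)
  }
  N <- MASS::Null(t(A))
  if (is.null(dim(N)) || ncol(N) == 0) {
    # fully determined system: a unique steady-state point (if in bounds)
    if (any(v_p < lb - 1e-9) || any(v_p > ub + 1e-9)) {
      stop("model is infeasible: the unique steady-state point violates ",
           "the flux bounds", call. = FALSE)
    }
    return(flux_samples_point(model, v_p, n_samples, tol))
  }
  v0 <- find_feasible_point(N, lb, ub, model$reactions$rxn_id,
                            v_offset = v_p)
  k <- ncol(N)

  # walk in null-space coordinates alpha (v = v_p + N alpha exactly at
  # every iterate), so steady state can never drift
  alpha0 <- as.vector(crossprod(N, v0 - v_p))
  withr::with_seed(seed, {
    alpha <- alpha0
    v <- v_p + as.vector(N %*% alpha)
    center <- alpha
    n_stored <- min(200L, n_samples)
    stored <- matrix(rep(alpha, n_stored), ncol = k, byrow = TRUE)
    samples <- matrix(NA_real_, n_samples, r,
                      dimnames = list(NULL, model$reactions$rxn_id))
    total_iter <- burn_in + n_samples * thin
    recorded <- 0L
    degenerate_run <- 0L
    i <- 0L
    while (recorded < n_samples) {
      i <- i + 1L
      if (i > burn_in && degenerate_run == 0L) {
        d <- stored[sample.int(n_stored, 1L), ] - center
        if (sqrt(sum(d^2)) < 1e-10) d <- stats::rnorm(k)
      } else {
        d <- stats::rnorm(k)
      }
      d <- d / sqrt(sum(d^2))   # N is orthonormal: |N d| = |d|
      w <- as.vector(N %*% d)
      act <- abs(w) > 1e-12
      lam_lo <- (lb[act] - v[act]) / w[act]
      lam_hi <- (ub[act] - v[act]) / w[act]
      lam_min <- max(pmin(lam_lo, lam_hi))
      lam_max <- min(pmax(lam_lo, lam_hi))
      if (!is.finite(lam_min) || !is.finite(lam_max) ||
          lam_max - lam_min < 1e-12) {
        degenerate_run <- degenerate_run + 1L
        if (degenerate_run >= 100L) {
          # no direction admits a chord: the polytope is a single point
          return(flux_samples_point(model, v, n_samples, tol,
                                    seed_used = seed))
        }
        next
      }
      degenerate_run <- 0L
      margin <- 1e-12 * (lam_max - lam_min)
      lam <- stats::runif(1, lam_min + margin, lam_max - margin)
      alpha <- alpha + lam * d
      v <- v_p + as.vector(N %*% alpha)
      center <- center + (alpha - center) / (i + 1)
      stored[(i %% n_stored) + 1L, ] <- alpha
      if (i > burn_in && (i - burn_in) %% thin == 0L) {
        recorded <- recorded + 1L
        samples[recorded, ] <- v
      }
      if (i > 100L * total_iter) {
        stop("sampler failed to make progress (", recorded, "/",
             n_samples, " samples after ", i, " iterations); the ",
             "polytope may be numerically degenerate", call. = FALSE)
      }
    }
    residuals <- apply(abs(S %*% t(samples)), 2, max)
    if (any(residuals > tol)) {
      stop("steady-state residual exceeded tolerance (max ",
           format(max(residuals)), " > ", format(tol), ")", call. = FALSE)
    }
    structure(list(samples = samples, residuals = residuals, model = model,
                   point_polytope = FALSE, method = method, seed = seed,
                   burn_in = burn_in, thin = thin),
              class = "flux_samples")
  })
}

flux_samples_point <- function(model, v, n_samples, tol, seed_used = NA) {
  res <- max(abs(model$S %*% v))
  if (res > tol) {
    stop("steady-state residual of the unique feasible point exceeds ",
         "tolerance", call. = FALSE)
  }
  samples <- matrix(rep(v, each = n_samples), n_samples, length(v),
                    dimnames = list(NULL, model$reactions$rxn_id))
  structure(list(samples = samples, residuals = rep(res, n_samples),
                 model = model, point_polytope = TRUE, method = "achr",
                 seed = seed_used, burn_in = 0, thin = 1),
            class = "flux_samples")
}

# Feasible point inside {lb <= v_offset + N alpha <= ub}: least-squares
# projection of the bound midpoint onto the null-space parameterization,
# refined by a smooth penalty minimization when the projection violates a
# bound. This doubles as the feasibility check: an irreducible violation
# means the steady-state constraints and the bounds are inconsistent.
find_feasible_point <- function(N, lb, ub, rxn_ids, v_offset = 0,
                                tol = 1e-9) {
  big <- 1e3
  mid <- (pmax(lb, -big) + pmin(ub, big)) / 2
  alpha <- qr.coef(qr(N), mid - v_offset)
  alpha[is.na(alpha)] <- 0
  violation <- function(a) {
    v <- v_offset + as.vector(N %*% a)
    max(c(lb - v, v - ub, 0))
  }
  if (violation(alpha) > tol) {
    pen <- function(a) {
      v <- v_offset + as.vector(N %*% a)
      sum(pmax(lb - v, 0)^2) + sum(pmax(v - ub, 0)^2)
    }
    gr <- function(a) {
      v <- v_offset + as.vector(N %*% a)
      g <- -2 * pmax(lb - v, 0) + 2 * pmax(v - ub, 0)
      as.vector(crossprod(N, g))
    }
    opt <- stats::optim(alpha, pen, gr, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-14))
    alpha <- opt$par
  }
  excess <- violation(alpha)
  if (excess > 1e-6) {
    v <- v_offset + as.vector(N %*% alpha)
    worst <- which.max(pmax(lb - v, v - ub))
    stop("model is infeasible: no steady-state flux vector satisfies the ",
         "bounds (worst violation ", format(excess), " at reaction ",
         rxn_ids[worst], ")", call. = FALSE)
  }
  v_offset + as.vector(N %*% alpha)
}

#' @export
print.flux_samples <- function(x, ...) {
  cat("Flux samples:", nrow(x$samples), "samples x", ncol(x$samples),
      "reactions\n")
  cat("  max steady-state residual:", format(max(x$residuals)), "\n")
  if (x$point_polytope) {
    cat("  polytope is a single point (fully determined fluxes)\n")
  }
  invisible(x)
}

#' Reactions with no sampled flux variability
#'
#' Reactions whose flux magnitude never exceeds `tol` across all samples
#' are effectively blocked under the model bounds (their Pearson
#' correlation with anything is undefined). Detection is sample-based: a
#' reaction reported here cannot carry flux anywhere the sampler visited.
#'
#' @param samples A [sample_fluxes()] result.
#' @param tol Flux magnitude below which a reaction counts as carrying no
#'   flux.
#' @return Character vector of reaction ids.
#' @export
blocked_reactions <- function(samples, tol = 1e-9) {
  stopifnot(inherits(samples, "flux_samples"))
  mx <- apply(abs(samples$samples), 2, max)
  names(mx)[mx <= tol]
}

#' Correlate sampled reaction fluxes with the target reaction
#'
#' Pearson correlation of every reaction's sampled flux with the target
#' reaction's flux. Reactions with (numerically) zero flux variance are
#' reported with `r = NA` and flagged rather than dropped; a zero-variance
#' target is an error because the whole analysis is then undefined
#' (typically the polytope collapsed to a point — relax the bounds).
#'
#' @param samples A [sample_fluxes()] result.
#' @param target_reaction_id Reaction to correlate against; defaults to the
#'   model's target reaction.
#' @return Data frame with columns `rxn_id`, `subsystem`, `r`,
#'   `zero_variance`, carrying attributes `target` and `n_samples`.
#' @export
correlate_with_target <- function(samples, target_reaction_id = NULL) {
  stopifnot(inherits(samples, "flux_samples"))
  X <- samples$samples
  if (is.null(target_reaction_id)) {
    target_reaction_id <- samples$model$target_reaction
  }
  if (!target_reaction_id %in% colnames(X)) {
    stop("target reaction '", target_reaction_id, "' not in the sample ",
         "matrix", call. = FALSE)
  }
  sds <- apply(X, 2, stats::sd)
  scale_ref <- pmax(abs(colMeans(X)), 1)
  zero_var <- sds <= 1e-12 * scale_ref
  if (zero_var[[target_reaction_id]]) {
    stop("target reaction flux has zero variance across samples; the ",
         "polytope is degenerate along the target — relax the model ",
         "bounds", call. = FALSE)
  }
  tv <- X[, target_reaction_id]
  r <- rep(NA_real_, ncol(X))
  r[!zero_var] <- as.vector(stats::cor(X[, !zero_var, drop = FALSE], tv))
  out <- data.frame(rxn_id = colnames(X),
                    subsystem = samples$model$reactions$subsystem[
                      match(colnames(X), samples$model$reactions$rxn_id)],
                    r = r, zero_variance = zero_var,
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "target") <- target_reaction_id
  attr(out, "n_samples") <- nrow(X)
  out
}

#' Classify flux correlations and summarize by subsystem
#'
#' Labels each reaction `positive` (`r >= threshold`), `negative`
#' (`r <= -threshold`) or `uncorrelated` (everything else, including
#' zero-variance reactions), and tabulates the classes per subsystem. The
#' raw `r` column is retained so counts can be recomputed at any other
#' threshold.
#'
#' @param report A [correlate_with_target()] result.
#' @param threshold Absolute correlation defining "linearly correlated",
#'   in (0, 1); default 0.7.
#' @return List of class `correlation_classification` with `report` (the
#'   input plus a `class` column) and `subsystem_summary` (counts of
#'   positive / negative / uncorrelated per subsystem).
#' @export
classify_correlations <- function(report, threshold = 0.7) {
  stopifnot(is.data.frame(report),
            all(c("rxn_id", "subsystem", "r") %in% names(report)))
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold <= 0 || threshold > 1) {
    stop("threshold must be a single value in (0, 1]", call. = FALSE)
  }
  cls <- rep("uncorrelated", nrow(report))
  cls[!is.na(report$r) & report$r >= threshold] <- "positive"
  cls[!is.na(report$r) & report$r <= -threshold] <- "negative"
  report$class <- factor(cls, levels = c("positive", "negative",
                                         "uncorrelated"))
  tab <- table(subsystem = report$subsystem, class = report$class)
  summary_df <- as.data.frame.matrix(tab)
  summary_df <- cbind(subsystem = rownames(summary_df), summary_df)
  rownames(summary_df) <- NULL
  structure(list(report = report, subsystem_summary = summary_df,
                 threshold = threshold),
            class = "correlation_classification")
}

#' @export
print.correlation_classification <- function(x, ...) {
  cat("Flux correlation classification (|r| >=", x$threshold, ")\n")
  print(x$subsystem_summary, row.names = FALSE)
  invisible(x)
}
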