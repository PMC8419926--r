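#' Aggregate strand-specific insertion profiles around motif instances
#'
#' For every motif instance the per-base + and - strand insertion counts
#' over offsets `[-flank, flank]` are collected in the motif frame: offsets
#' increase towards the motif's 3' side, and for a minus-strand match the
#' offsets are negated and the strand labels swapped (reverse-complement
#' orientation). The aggregate profile is the per-offset mean over
#' instances. Protein-bound sites show an asymmetric pattern — elevated
#' oriented-+ cuts 5' of the motif and oriented-- cuts 3' of it — whereas
#' naked DNA and unbound sites are mirror-symmetric in expectation.
#'
#' Instances whose flank extends beyond the chromosome are dropped (their
#' number is recorded in `n_dropped`).
#'
#' @param track a `fatac_track`.
#' @param instances tibble of motif instances (chrom, start, end, strand).
#' @param flank half-width of the window in bp (default 100).
#' @return object of class `fatac_strand_profile`: `profile` tibble (offset,
#'   f_plus, f_minus: mean insertions per instance per base), `n_instances`,
#'   `n_dropped`, `total_insertions`, `flank`, and the per-instance count
#'   matrices needed by the permutation and bootstrap machinery.
#' @export
strand_profiles <- function(track, instances, flank = 100L) {
  if (nrow(instances) == 0) abort("no motif instances supplied")
  width <- 2L * flank + 1L
  keep <- logical(nrow(instances))
  P <- matrix(0L, nrow(instances), width)
  M <- matrix(0L, nrow(instances), width)
  for (i in seq_len(nrow(instances))) {
    ch <- instances$chrom[i]
    L <- track$chrom_lengths[[ch]]
    center <- (instances$start[i] + instances$end[i]) %/% 2L
    if (center - flank < 0 || center + flank >= L) next
    keep[i] <- TRUE
    idx <- (center - flank + 1L):(center + flank + 1L) # 1-based
    vp <- track$counts[[ch]]$plus[idx]
    vm <- track$counts[[ch]]$minus[idx]
    if (instances$strand[i] == "+") {
      P[i, ] <- vp
      M[i, ] <- vm
    } else {
      P[i, ] <- rev(vm)
      M[i, ] <- rev(vp)
    }
  }
  P <- P[keep, , drop = FALSE]
  M <- M[keep, , drop = FALSE]
  n <- nrow(P)
  if (n == 0) abort("all instances dropped (flanks exceed chromosome bounds)")
  structure(
    list(
      profile = tibble(
        offset = -flank:flank,
        f_plus = colSums(P) / n,
        f_minus = colSums(M) / n
      ),
      n_instances = n,
      n_dropped = sum(!keep),
      total_insertions = sum(P) + sum(M),
      flank = flank,
      instance_plus = P,
      instance_minus = M
    ),
    class = "fatac_strand_profile"
  )
}

#' @export
print.fatac_strand_profile <- function(x, ...) {
  cat("<fatac_strand_profile> ", x$n_instances, " instances, flank ",
      x$flank, " bp, ", x$total_insertions, " insertions\n", sep = "")
  invisible(x)
}

#' @method tidy fatac_strand_profile
#' @export
tidy.fatac_strand_profile <- function(x, ...) x$profile

#' Mirror-asymmetry statistic S
#'
#' Normalises each strand profile to a probability distribution over
#' offsets and returns the total-variation distance between the + profile
#' and the offset-mirrored - profile:
#' `S = 1/2 * sum_x |g_plus(x) - g_minus(-x)|`, in \[0, 1\].
#' Under the reverse-complement symmetry of Tn5 integration into naked DNA,
#' `E f_plus(x) = E f_minus(-x)` and S converges to 0; protein binding
#' breaks the symmetry and inflates S (S = 1 when the two distributions
#' have disjoint mirror support). The statistic is invariant to uniform
#' rescaling of the profiles.
#'
#' @param profile a `fatac_strand_profile`, or a tibble with f_plus/f_minus.
#' @return S in \[0, 1\].
#' @export
asymmetry_statistic <- function(profile) {
  pr <- if (inherits(profile, "fatac_strand_profile")) profile$profile else profile
  s <- s_from_sums(pr$f_plus, pr$f_minus)
  if (is.na(s)) abort("zero insertions: asymmetry statistic undefined")
  s
}

# S from raw summed strand vectors (internal fast path)
s_from_sums <- function(sp, sm) {
  if (sum(sp) <= 0 || sum(sm) <= 0) return(NA_real_)
  0.5 * sum(abs(sp / sum(sp) - rev(sm) / sum(sm)))
}

#' Permutation test for strand asymmetry at motif instances
#'
#' The null hypothesis is orientation-exchangeability: each instance's
#' profile pair is flipped (offsets negated, strand labels swapped) with
#' probability 1/2, which preserves every instance's total signal and
#' positional clustering while destroying the strand/orientation coupling
#' that protein binding creates. `p_perm = (1 + #\{S_null >= S_obs\}) /
#' (n_perm + 1)`.
#'
#' The call is `"bound"` when `p_perm < alpha` and, if control profiles are
#' supplied (TF-deletion or naked-DNA conditions), `S_obs` also exceeds the
#' 95th bootstrap percentile of every control's S; `"indeterminate"` when
#' the controls disagree on exceedance; `"unbound"` when `p_perm >= alpha`.
#'
#' @param track a `fatac_track`.
#' @param instances motif-instance tibble.
#' @param flank window half-width in bp.
#' @param n_perm number of orientation permutations (>= 100).
#' @param seed RNG seed.
#' @param controls optional `fatac_strand_profile` or list of them.
#' @param alpha significance level (default 0.05).
#' @param n_boot bootstrap resamples per control (default 200).
#' @return object of class `fatac_asymmetry`: S_obs, p_perm, n_perm,
#'   delta_vs_control (S_obs minus the largest control S; NA without
#'   controls), call, control_q95, profile.
#' @export
permutation_test <- function(track, instances, flank = 100L, n_perm = 1000L,
                             seed = 1, controls = NULL, alpha = 0.05,
                             n_boot = 200L) {
  if (n_perm < 100) abort("n_perm must be >= 100 (resolution floor)")
  prof <- strand_profiles(track, instances, flank)
  asymmetry_test_profile(prof, n_perm = n_perm, seed = seed,
                         controls = controls, alpha = alpha, n_boot = n_boot)
}

#' Permutation test on a precomputed strand profile
#'
#' Same test as [permutation_test()] but starting from a
#' `fatac_strand_profile`, which is convenient when profiles are reused
#' across conditions.
#'
#' @inheritParams permutation_test
#' @param profile a `fatac_strand_profile`.
#' @export
asymmetry_test_profile <- function(profile, n_perm = 1000L, seed = 1,
                                   controls = NULL, alpha = 0.05,
                                   n_boot = 200L) {
  if (n_perm < 100) abort("n_perm must be >= 100 (resolution floor)")
  P <- profile$instance_plus
  M <- profile$instance_minus
  n <- nrow(P)
  S_obs <- s_from_sums(colSums(P), colSums(M))
  if (is.na(S_obs)) {
    if (sum(P) + sum(M) == 0) abort("zero insertions: asymmetry statistic undefined")
    # signal confined to one strand entirely: no power, conservative call
    return(structure(
      list(S_obs = NA_real_, p_perm = 1, n_perm = as.integer(n_perm),
           delta_vs_control = NA_real_, call = "unbound",
           control_q95 = NULL, S_null = rep(NA_real_, n_perm),
           n_instances = profile$n_instances, profile = profile$profile),
      class = "fatac_asymmetry"
    ))
  }

  # flipping instance i replaces (p_i(x), m_i(x)) by (m_i(-x), p_i(-x))
  Prev <- P[, ncol(P):1, drop = FALSE]
  Mrev <- M[, ncol(M):1, drop = FALSE]
  S_null <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      flip <- runif(n) < 0.5
      sp <- colSums(P[!flip, , drop = FALSE]) + colSums(Mrev[flip, , drop = FALSE])
      sm <- colSums(M[!flip, , drop = FALSE]) + colSums(Prev[flip, , drop = FALSE])
      s_from_sums(sp, sm)
    }, numeric(1))
  })
  p_perm <- (1 + sum(S_null >= S_obs)) / (n_perm + 1)

  if (!is.null(controls) && inherits(controls, "fatac_strand_profile")) {
    controls <- list(controls)
  }
  control_q95 <- NULL
  delta <- NA_real_
  call <- if (p_perm < alpha) "bound" else "unbound"
  if (p_perm < alpha && length(controls) > 0) {
    control_q95 <- vapply(seq_along(controls), function(ci) {
      bootstrap_s(controls[[ci]], n_boot, derive_seed(seed, paste0("ctl", ci)))$q95
    }, numeric(1))
    exceeds <- S_obs > control_q95
    call <- if (all(exceeds)) "bound" else if (any(exceeds)) "indeterminate" else "unbound"
    S_ctl <- vapply(controls, asymmetry_statistic, numeric(1))
    delta <- S_obs - max(S_ctl)
  }
  structure(
    list(
      S_obs = S_obs, p_perm = p_perm, n_perm = as.integer(n_perm),
      delta_vs_control = delta, call = call,
      control_q95 = control_q95, S_null = S_null,
      n_instances = profile$n_instances, profile = profile$profile
    ),
    class = "fatac_asymmetry"
  )
}

# instance-level bootstrap of S for one profile
bootstrap_s <- function(profile, n_boot, seed) {
  P <- profile$instance_plus
  M <- profile$instance_minus
  n <- nrow(P)
  s_boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, n, replace = TRUE)
      s_from_sums(colSums(P[idx, , drop = FALSE]), colSums(M[idx, , drop = FALSE]))
    }, numeric(1))
  })
  s_boot <- s_boot[!is.na(s_boot)]
  list(boot = s_boot, se = sd(s_boot),
       q95 = as.numeric(quantile(s_boot, 0.95)))
}

#' Bootstrap standard error of the asymmetry statistic
#'
#' @param profile a `fatac_strand_profile`.
#' @param n_boot number of instance-level resamples (default 1000).
#' @param seed RNG seed.
#' @return tibble: S, se, q05, q95.
#' @export
asymmetry_se <- function(profile, n_boot = 1000L, seed = 1) {
  bs <- bootstrap_s(profile, n_boot, seed)
  tibble(
    S = asymmetry_statistic(profile),
    se = bs$se,
    q05 = as.numeric(quantile(bs$boot, 0.05)),
    q95 = bs$q95
  )
}

#' @export
print.fatac_asymmetry <- function(x, ...) {
  cat("<fatac_asymmetry> S = ", format(x$S_obs, digits = 4),
      ", p_perm = ", format(x$p_perm, digits = 4),
      " (", x$n_perm, " permutations), call: ", x$call, "\n", sep = "")
  invisible(x)
}

#' @method tidy fatac_asymmetry
#' @export
tidy.fatac_asymmetry <- function(x, ...) {
  tibble(
    S_obs = x$S_obs, p_perm = x$p_perm, n_perm = x$n_perm,
    delta_vs_control = x$delta_vs_control, call = x$call,
    n_instances = x$n_instances
  )
}

#' @method glance fatac_asymmetry
#' @export
glance.fatac_asymmetry <- function(x, ...) tidy(x)

#' Compare asymmetry between a test and a control condition
#'
#' `delta = S_test - S_control` with a 95% confidence interval from
#' independent instance-level bootstraps of the two profiles.
#'
#' @param profile_test,profile_control `fatac_strand_profile` objects over
#'   the same flank.
#' @param n_boot bootstrap resamples (default 1000).
#' @param seed RNG seed.
#' @return tibble: S_test, S_control, delta, ci_lo, ci_hi.
#' @export
compare_conditions <- function(profile_test, profile_control, n_boot = 1000L,
                               seed = 1) {
  if (profile_test$flank != profile_control$flank) {
    abort("profiles computed over different flanks")
  }
  bt <- bootstrap_s(profile_test, n_boot, derive_seed(seed, "test"))
  bc <- bootstrap_s(profile_control, n_boot, derive_seed(seed, "control"))
  m <- min(length(bt$boot), length(bc$boot))
  deltas <- bt$boot[seq_len(m)] - bc$boot[seq_len(m)]
  ci <- as.numeric(quantile(deltas, c(0.025, 0.975)))
  tibble(
    S_test = asymmetry_statistic(profile_test),
    S_control = asymmetry_statistic(profile_control),
    delta = asymmetry_statistic(profile_test) - asymmetry_statistic(profile_control),
    ci_lo = ci[1], ci_hi = ci[2]
  )
}
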