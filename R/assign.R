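#' Expected LogR of a copy-number state under the purity/ploidy mixture
#'
#' A segment at tumour copy number `cn` in a sample of purity `rho` and
#' ploidy `psi` has expected LogR `log2((2 * (1 - rho) + rho * cn) / psi)`:
#' host cells contribute two copies, tumour cells `cn`, and the profile is
#' normalised to the sample's baseline ploidy. At `cn = 0, rho = 1` the
#' mixture is empty and `-Inf` is returned.
#'
#' @param cn Copy number (>= 0), vectorised.
#' @param rho Purity in (0, 1].
#' @param psi Baseline ploidy (2 or 4).
#' @return Expected LogR.
#' @export
logr_expected <- function(cn, rho, psi = 2) {
  stopifnot(all(cn >= 0), rho > 0, rho <= 1)
  arg <- (2 * (1 - rho) + rho * cn) / psi
  ifelse(arg > 0, log2(arg), -Inf)
}

#' Continuous copy number from LogR (exact inverse of [logr_expected()])
#'
#' @param r_s Segment LogR.
#' @param rho Purity in (0, 1].
#' @param psi Baseline ploidy.
#' @return Continuous copy number (may be negative for noisy near-zero
#'   segments; callers clip at 0).
#' @export
cn_from_logr <- function(r_s, rho, psi = 2) {
  stopifnot(rho > 0)
  (psi * 2^r_s - 2 * (1 - rho)) / rho
}

rhat_split <- function(chains) {
  # split-Rhat over a list of equal-length chains
  half <- lapply(chains, function(ch) {
    n <- length(ch) %/% 2
    list(ch[seq_len(n)], ch[n + seq_len(n)])
  })
  cs <- unlist(half, recursive = FALSE)
  m <- length(cs)
  n <- length(cs[[1]])
  means <- vapply(cs, mean, 0)
  vars <- vapply(cs, stats::var, 0)
  B <- n * stats::var(means)
  W <- mean(vars)
  if (!is.finite(W) || W == 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Bayesian hierarchical copy-number fit by Gibbs/Metropolis sampling
#'
#' Model: `mean_logr_s ~ Normal(logr_expected(CN_s, rho, psi), sigma^2 / n_bins_s)`
#' with `CN_s` categorical uniform on 0..`max_cn`, `rho ~ Beta` centred at the
#' initial estimate with configurable concentration, `psi` uniform on {2, 4},
#' and `sigma^2` under a weak inverse-gamma prior. States and `sigma^2` are
#' Gibbs-updated; `rho` by a logit random-walk Metropolis step; `psi` by a
#' marginal (state-integrated) draw. Convergence is monitored by split-R-hat
#' on `rho` across chains; a value above 1.1 sets `converged = FALSE` rather
#' than raising an error.
#'
#' @param segments Segment table (`mean_logr`, `n_bins`).
#' @param init_rho Initial purity (a number or `purity_estimate`).
#' @param max_cn Highest state considered (default 9).
#' @param psi_fixed Optional known ploidy (2 or 4) from karyotype flags;
#'   `NULL` samples psi over {2, 4}.
#' @param n_iter Iterations per chain (default 5000).
#' @param burn_in Burn-in iterations (default 1000).
#' @param n_chains Number of chains (default 4).
#' @param rho_concentration Beta prior concentration (default 50).
#' @param psi_prior Prior mass on ploidy 2 vs 4 (default c(0.9, 0.1)):
#'   a doubled-state tetraploid profile is likelihood-identical to a diploid
#'   one, so the prior breaks the tie toward the parsimonious diploid
#'   baseline; genuine tetraploids are identified by odd states at
#'   half spacing, which overwhelm the prior.
#' @param seed Integer seed.
#' @return List: `rho` (posterior mean), `rho_ci` (90% credible interval),
#'   `psi` (posterior mode), `states` (posterior-mode state per segment),
#'   `state_prob` (posterior frequency of the modal state), `sigma`,
#'   `converged`, `rhat`.
#' @export
fit_bayesian <- function(segments, init_rho, max_cn = 9, psi_fixed = NULL,
                         n_iter = 5000, burn_in = 1000, n_chains = 4,
                         rho_concentration = 50, psi_prior = c(0.9, 0.1),
                         seed = 1) {
  if (nrow(segments) < 2) stop("need at least 2 segments")
  rho0 <- if (inherits(init_rho, "purity_estimate")) init_rho$rho else init_rho
  if (is.null(rho0) || !is.finite(rho0)) stop("init_rho must be defined")
  rho0 <- min(0.99, max(0.05, rho0))
  x <- segments$mean_logr
  nb <- pmax(1, segments$n_bins)
  keep <- is.finite(x)
  x <- x[keep]; nb <- nb[keep]
  S <- length(x)
  states_grid <- 0:max_cn
  a_pr <- rho0 * rho_concentration
  b_pr <- (1 - rho0) * rho_concentration
  psis <- if (is.null(psi_fixed)) c(2, 4) else psi_fixed
  log_psi_prior <- if (length(psis) > 1) log(psi_prior / sum(psi_prior)) else 0
  loglik_matrix <- function(rho, psi, sigma) {
    mu <- logr_expected(states_grid, rho, psi)
    ll <- -0.5 * (outer(x, mu, "-") / (sigma / sqrt(nb)))^2 -
      log(sigma / sqrt(nb))
    ll[, !is.finite(mu)] <- -1e10
    ll
  }
  run_chain <- function() {
    rho <- min(0.99, max(0.05, rho0 * exp(stats::rnorm(1, 0, 0.05))))
    psi <- psis[1]
    sigma <- max(1e-4, stats::sd(x) / 2)
    st <- integer(S)
    rho_draw <- numeric(n_iter)
    psi_draw <- numeric(n_iter)
    sig_draw <- numeric(n_iter)
    st_count <- matrix(0L, S, length(states_grid))
    for (it in seq_len(n_iter)) {
      # psi: marginalise states under each candidate
      if (length(psis) > 1) {
        lm_psi <- vapply(psis, function(p) {
          ll <- loglik_matrix(rho, p, sigma)
          sum(apply(ll, 1, function(r) {
            m <- max(r); m + log(sum(exp(r - m)))
          }))
        }, 0)
        lm_psi <- lm_psi + log_psi_prior
        psi <- psis[sample.int(length(psis), 1,
                               prob = exp(lm_psi - max(lm_psi)))]
      }
      # states | rho, psi, sigma
      ll <- loglik_matrix(rho, psi, sigma)
      pm <- exp(ll - apply(ll, 1, max))
      cp <- t(apply(pm / rowSums(pm), 1, cumsum))
      u <- stats::runif(S)
      st <- rowSums(cp < u) + 1L # 1-based index into states_grid
      st <- pmin(st, length(states_grid))
      # sigma^2 | states (conjugate inverse-gamma)
      mu_s <- logr_expected(states_grid[st], rho, psi)
      res <- (x - mu_s) * sqrt(nb)
      res[!is.finite(res)] <- 0
      sigma <- sqrt(1 / stats::rgamma(1, 2 + S / 2, 0.02 + sum(res^2) / 2))
      sigma <- min(max(sigma, 1e-4), 5)
      # rho | states (logit random-walk Metropolis)
      logpost <- function(r) {
        if (r <= 0 || r >= 1) return(-Inf)
        mu <- logr_expected(states_grid[st], r, psi)
        if (any(!is.finite(mu) & is.finite(x))) return(-1e10)
        sum(-0.5 * ((x - mu) / (sigma / sqrt(nb)))^2) +
          stats::dbeta(r, a_pr, b_pr, log = TRUE)
      }
      lo <- stats::qlogis(rho)
      prop <- stats::plogis(lo + stats::rnorm(1, 0, 0.08))
      lr <- logpost(prop) - logpost(rho) +
        log(prop * (1 - prop)) - log(rho * (1 - rho)) # logit Jacobian
      if (is.finite(lr) && log(stats::runif(1)) < lr) rho <- prop
      rho_draw[it] <- rho
      psi_draw[it] <- psi
      sig_draw[it] <- sigma
      if (it > burn_in) st_count[cbind(seq_len(S), st)] <-
          st_count[cbind(seq_len(S), st)] + 1L
    }
    list(rho = rho_draw, psi = psi_draw, sigma = sig_draw, st_count = st_count)
  }
  with_seed(seed, {
    chains <- lapply(seq_len(n_chains), function(i) run_chain())
    post <- seq.int(burn_in + 1, n_iter)
    rho_all <- unlist(lapply(chains, function(c) c$rho[post]))
    psi_all <- unlist(lapply(chains, function(c) c$psi[post]))
    sig_all <- unlist(lapply(chains, function(c) c$sigma[post]))
    st_count <- Reduce(`+`, lapply(chains, function(c) c$st_count))
    modal <- max.col(st_count, ties.method = "first")
    rhat <- rhat_split(lapply(chains, function(c) c$rho[post]))
    states_full <- rep(NA_real_, nrow(segments))
    prob_full <- rep(NA_real_, nrow(segments))
    states_full[keep] <- states_grid[modal]
    prob_full[keep] <- st_count[cbind(seq_len(S), modal)] / rowSums(st_count)
    list(rho = mean(rho_all),
         rho_ci = unname(stats::quantile(rho_all, c(0.05, 0.95))),
         psi = as.numeric(names(sort(table(psi_all), decreasing = TRUE))[1]),
         states = states_full, state_prob = prob_full,
         sigma = mean(sig_all), rhat = rhat, converged = rhat <= 1.1)
  })
}

#' Poisson mixture copy-number assignment
#'
#' Cross-validates the Bayesian states: the mean per-bin read count of
#' segments provisionally at CN2 anchors the expected count `r_n` of each
#' state, and each segment takes the state maximising the Poisson
#' log-probability `k * log(r_n) - r_n - lgamma(k + 1)` at its observed mean
#' per-bin count `k`. `mode = "mixture"` (default) uses the host-dilution
#' form `r_n = k_tilde * (2 * (1 - rho) + n * rho) / 2`, consistent with the
#' LogR model; `mode = "as_printed"` uses `r_n = k_tilde * n * rho / 2`
#' (states 1..max_cn only, since `r_0 = 0`). Both coincide at `rho = 1`.
#'
#' @param seg_counts Mean per-bin read count of each segment.
#' @param provisional_cn2 Logical: which segments anchor `k_tilde`.
#' @param rho Purity.
#' @param mode "mixture" or "as_printed".
#' @param max_cn Highest state (default 9).
#' @return List of class `poisson_fit`: `k_tilde`, `r_n`, `states`, `logprob`
#'   (segments x states matrix).
#' @export
poisson_assign <- function(seg_counts, provisional_cn2, rho,
                           mode = c("mixture", "as_printed"), max_cn = 9) {
  mode <- match.arg(mode)
  provisional_cn2 <- !is.na(provisional_cn2) & provisional_cn2
  if (!any(provisional_cn2)) stop("no provisional CN2 segments to anchor k_tilde")
  k_tilde <- mean(seg_counts[provisional_cn2])
  if (!is.finite(k_tilde) || k_tilde <= 0) stop("undefined k_tilde")
  n_grid <- if (mode == "as_printed") seq_len(max_cn) else 0:max_cn
  r_n <- if (mode == "as_printed") k_tilde * n_grid * rho / 2
         else k_tilde * (2 * (1 - rho) + n_grid * rho) / 2
  lp <- sapply(r_n, function(r) {
    if (r <= 0) ifelse(seg_counts == 0, 0, -1e10)
    else seg_counts * log(r) - r - lgamma(seg_counts + 1)
  })
  lp <- matrix(lp, nrow = length(seg_counts))
  colnames(lp) <- paste0("cn", n_grid)
  states <- n_grid[max.col(lp, ties.method = "first")]
  structure(list(k_tilde = k_tilde, r_n = stats::setNames(r_n, paste0("cn", n_grid)),
                 states = states, logprob = lp, mode = mode),
            class = "poisson_fit")
}

#' Reconcile Bayesian and Poisson state assignments
#'
#' Agreeing segments take the shared integer. Disagreeing segments take the
#' Bayesian state and are flagged. A segment whose continuous copy number
#' lies within `tol` of the half-integer midpoint between the two candidate
#' integers is labelled subclonal at that half-integer.
#'
#' @param bayes_states,poisson_states Integer states per segment.
#' @param segments Segment table (`mean_logr`).
#' @param rho,psi Purity and ploidy used for the continuous copy number.
#' @param tol Half-integer window (default 0.15).
#' @return `segments` with `cn_state`, `subclonal`, and `flagged` columns.
#' @export
reconcile <- function(bayes_states, poisson_states, segments, rho, psi = 2,
                      tol = 0.15) {
  stopifnot(length(bayes_states) == nrow(segments),
            length(poisson_states) == nrow(segments))
  cont <- pmax(0, cn_from_logr(segments$mean_logr, rho, psi))
  state <- bayes_states
  flagged <- rep(FALSE, nrow(segments))
  subclonal <- rep(FALSE, nrow(segments))
  disagree <- which(is.finite(bayes_states) & is.finite(poisson_states) &
                      bayes_states != poisson_states)
  for (i in disagree) {
    mid <- (bayes_states[i] + poisson_states[i]) / 2
    if (abs(bayes_states[i] - poisson_states[i]) == 1 &&
        abs(cont[i] - mid) <= tol) {
      state[i] <- mid
      subclonal[i] <- TRUE
    } else {
      flagged[i] <- TRUE # keep the Bayesian state, mark for review
    }
  }
  segments$cn_state <- state
  segments$subclonal <- subclonal
  segments$flagged <- flagged
  segments
}

#' Full copy-number assignment for one sample
#'
#' Runs the Bayesian fit, anchors the Poisson mixture on the Bayesian CN2
#' segments, reconciles the two assignments, and merges adjacent segments
#' left at the same state (removing residual false-positive breakpoints).
#'
#' @param segments Segment table for one sample.
#' @param seg_counts Mean per-bin read count per segment.
#' @param init_rho Initial purity estimate.
#' @param psi_fixed Known ploidy or `NULL`.
#' @param mode Poisson mode; see [poisson_assign()].
#' @param seed Integer seed.
#' @param ... Passed to [fit_bayesian()].
#' @return List: `segments` (with final states), `fit` (Bayesian fit),
#'   `poisson` (`poisson_fit`).
#' @export
assign_copy_number <- function(segments, seg_counts, init_rho, psi_fixed = NULL,
                               mode = "mixture", seed = 1, ...) {
  fit <- fit_bayesian(segments, init_rho, psi_fixed = psi_fixed, seed = seed, ...)
  anchor <- fit$states == 2
  if (!any(anchor, na.rm = TRUE)) anchor <- fit$states == fit$psi
  pois <- poisson_assign(seg_counts, !is.na(anchor) & anchor, fit$rho, mode = mode)
  seg <- reconcile(fit$states, pois$states, segments, fit$rho, fit$psi)
  seg <- merge_same_state(seg)
  list(segments = seg, fit = fit, poisson = pois)
}

# merge adjacent segments with identical final state within sample/chromosome
merge_same_state <- function(seg) {
  out <- list()
  for (key in unique(paste(seg$sample, seg$chrom))) {
    s <- seg[paste(seg$sample, seg$chrom) == key, , drop = FALSE]
    s <- s[order(s$start), , drop = FALSE]
    i <- 1
    while (i < nrow(s)) {
      if (!is.na(s$cn_state[i]) && !is.na(s$cn_state[i + 1]) &&
          s$cn_state[i] == s$cn_state[i + 1] && s$end[i] == s$start[i + 1]) {
        w <- c(s$n_bins[i], s$n_bins[i + 1])
        s$mean_logr[i] <- stats::weighted.mean(s$mean_logr[i:(i + 1)], w + 1e-9)
        s$end[i] <- s$end[i + 1]
        s$n_bins[i] <- sum(w)
        s$flagged[i] <- s$flagged[i] || s$flagged[i + 1]
        s <- s[-(i + 1), , drop = FALSE]
      } else i <- i + 1
    }
    out[[key]] <- s
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
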