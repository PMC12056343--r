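# Blocked conjugate Gibbs sampler for the heteroscedastic timing model:
#
#   y_i = x_i' beta + u_site(s_i) + u_date(d_i) + b(j_i) + e_i
#   b_j ~ N(0, sigma_B[habitat_j]^2)     (between-individual, per habitat)
#   e_i ~ N(0, sigma_W[habitat_i]^2)     (within-individual, per habitat)
#
# Two-block scheme: (1) all location parameters (beta, site, date and bird
# intercepts) are drawn jointly from their exact multivariate-normal full
# conditional, exploiting the diagonal bird block of the joint precision
# via a Schur complement, so the weakly identified habitat/site/bird-mean
# directions mix freely; (2) variance components are drawn from their
# inverse-gamma conditionals. All SDs carry half-t(3, A) priors through the
# Huang-Wand inverse-gamma mixture (sigma^2 | a ~ IG(nu/2, nu/a),
# a ~ IG(1/2, 1/A^2)); fixed effects carry weakly-informative normal
# priors.

rinvgamma1 <- function(shape, rate) 1 / rgamma(1L, shape = shape, rate = rate)

# One half-t SD update (Huang-Wand): returns c(sigma2, a).
update_sd <- function(ss, m, a, A, nu = 3) {
  sigma2 <- rinvgamma1((nu + m) / 2, nu / a + ss / 2)
  a_new <- rinvgamma1((nu + 1) / 2, nu / sigma2 + 1 / A^2)
  c(sigma2, a_new)
}

# Joint multiplicative rescale (u, sigma^2) -> (c u, c^2 sigma^2) for one
# random-effect block, a Metropolis move along the funnel axis that
# unsticks near-zero variance components. r_nd is the residual with this
# block's contribution added back; tau_w the per-observation precision.
# Returns list(u, sigma2, accepted).
rescale_move <- function(u, g, sigma2, a, r_nd, tau_w, nu = 3, step = 0.4) {
  lc <- rnorm(1, 0, step)
  c_ <- exp(lc)
  ui <- u[g]
  A1 <- sum(tau_w * ui^2)
  A2 <- sum(tau_w * r_nd * ui)
  dloglik <- -0.5 * ((c_^2 - 1) * A1 - 2 * (c_ - 1) * A2)
  dlogprior <- -nu * lc - nu / (a * sigma2) * (1 / c_^2 - 1)
  if (is.finite(dloglik + dlogprior) &&
      log(runif(1)) < dloglik + dlogprior) {
    list(u = c_ * u, sigma2 = c_^2 * sigma2, accepted = TRUE)
  } else {
    list(u = u, sigma2 = sigma2, accepted = FALSE)
  }
}

#' @keywords internal
gibbs_hetero_lmm <- function(y, X, site, date, bird, hab_obs, hab_bird,
                             chains = 4L, iter = 2000L, warmup = 500L,
                             seed = 1L, A_scale = NULL, A_scale_nuis = NULL,
                             beta_sd = NULL) {
  n <- length(y)
  p <- ncol(X)
  Ks <- max(site)
  Kd <- max(date)
  Kb <- max(bird)
  sdy <- sd(y)
  if (is.null(A_scale)) A_scale <- 2.5 * sdy
  # site and date are few-level nuisance intercepts; a unit-scale half-t
  # would let their heavy tail dominate habitat contrasts, so their prior
  # scale is tighter than the focal bird/residual SDs
  if (is.null(A_scale_nuis)) A_scale_nuis <- 0.5 * sdy
  if (is.null(beta_sd)) beta_sd <- 10 * max(sdy, 1)

  # dense design of all non-bird location parameters
  Zs <- matrix(0, n, Ks); Zs[cbind(seq_len(n), site)] <- 1
  Zd <- matrix(0, n, Kd); Zd[cbind(seq_len(n), date)] <- 1
  F <- cbind(X, Zs, Zd)
  q <- ncol(F)
  i_site <- p + seq_len(Ks)
  i_date <- p + Ks + seq_len(Kd)

  # per-habitat sufficient statistics (habitat codes: 1 urban, 2 forest)
  FtF <- lapply(1:2, function(h) crossprod(F[hab_obs == h, , drop = FALSE]))
  Fty <- lapply(1:2, function(h) crossprod(F[hab_obs == h, , drop = FALSE],
                                           y[hab_obs == h]))
  G <- t(rowsum(F, bird))             # q x Kb: per-bird column sums of F
  ysum_b <- drop(rowsum(y, bird))
  n_b <- tabulate(bird, Kb)
  n_h <- tabulate(hab_obs, 2L)
  m_bh <- tabulate(hab_bird, 2L)

  pn <- c(colnames(X), "sigma_site", "sigma_date",
          "sigma_B_urban", "sigma_B_forest",
          "sigma_W_urban", "sigma_W_forest")
  draws <- matrix(NA_real_, chains * iter, length(pn),
                  dimnames = list(NULL, pn))
  chain_id <- rep(seq_len(chains), each = iter)

  for (ch in seq_len(chains)) {
    set.seed(substream_seed(seed, paste0("gibbs-chain-", ch)))
    # dispersed variance initials; locations are drawn first each sweep
    s2_site <- runif(1, 0.01, 0.5)^2
    s2_date <- runif(1, 0.01, 0.5)^2
    s2_B <- runif(2, 0.2 * sdy, sdy)^2
    s2_W <- runif(2, 0.3 * sdy, 1.5 * sdy)^2
    a_site <- a_date <- 1
    a_B <- a_W <- c(1, 1)

    for (it in seq_len(warmup + iter)) {
      tau_W <- 1 / s2_W
      # --- joint draw of (beta, u_site, u_date, b) ---
      prior_f <- c(rep(1 / beta_sd^2, p), rep(1 / s2_site, Ks),
                   rep(1 / s2_date, Kd))
      Pff <- FtF[[1]] * tau_W[1] + FtF[[2]] * tau_W[2]
      diag(Pff) <- diag(Pff) + prior_f
      scale_b <- tau_W[hab_bird]
      Pfb <- G * rep(scale_b, each = q)
      D <- n_b * scale_b + 1 / s2_B[hab_bird]
      PfbD <- Pfb * rep(1 / D, each = q)
      S <- Pff - tcrossprod(PfbD, Pfb)
      rf <- Fty[[1]] * tau_W[1] + Fty[[2]] * tau_W[2]
      rb <- ysum_b * scale_b
      U <- chol(S)
      mf <- backsolve(U, forwardsolve(t(U), rf - PfbD %*% rb))
      f <- drop(mf + backsolve(U, rnorm(q)))
      b_mean <- (rb - drop(crossprod(Pfb, f))) / D
      b <- rnorm(Kb, b_mean, sqrt(1 / D))

      u_site <- f[i_site]
      u_date <- f[i_date]
      resid <- y - drop(F %*% f) - b[bird]
      tau_obs <- tau_W[hab_obs]

      # --- variance draws, with funnel rescale moves for site/date ---
      up <- update_sd(sum(u_site^2), Ks, a_site, A_scale_nuis)
      s2_site <- up[1]; a_site <- up[2]
      r_nd <- resid + u_site[site]
      for (stp in c(0.25, 0.6, 1.5)) {
        mv <- rescale_move(u_site, site, s2_site, a_site, r_nd, tau_obs,
                           step = stp)
        u_site <- mv$u; s2_site <- mv$sigma2
      }
      resid <- r_nd - u_site[site]

      up <- update_sd(sum(u_date^2), Kd, a_date, A_scale_nuis)
      s2_date <- up[1]; a_date <- up[2]
      r_nd <- resid + u_date[date]
      for (stp in c(0.25, 0.6, 1.5)) {
        mv <- rescale_move(u_date, date, s2_date, a_date, r_nd, tau_obs,
                           step = stp)
        u_date <- mv$u; s2_date <- mv$sigma2
      }
      resid <- r_nd - u_date[date]

      for (h in 1:2) {
        up <- update_sd(sum(b[hab_bird == h]^2), m_bh[h], a_B[h], A_scale)
        s2_B[h] <- up[1]; a_B[h] <- up[2]
      }
      # funnel rescale for each habitat's bird block
      r_nd <- resid + b[bird]
      for (h in 1:2) {
        io <- hab_obs == h
        jb <- hab_bird == h
        bh <- b
        bh[!jb] <- 0  # only habitat-h birds rescale
        for (stp in c(0.3, 0.9)) {
          mv <- rescale_move(bh, bird[io], s2_B[h], a_B[h], r_nd[io],
                             rep(tau_W[h], sum(io)), step = stp)
          bh <- mv$u; s2_B[h] <- mv$sigma2
        }
        b[jb] <- bh[jb]
      }
      resid <- r_nd - b[bird]
      for (h in 1:2) {
        up <- update_sd(sum(resid[hab_obs == h]^2), n_h[h], a_W[h], A_scale)
        s2_W[h] <- up[1]; a_W[h] <- up[2]
      }

      if (it > warmup) {
        draws[(ch - 1L) * iter + (it - warmup), ] <-
          c(f[seq_len(p)], sqrt(s2_site), sqrt(s2_date),
            sqrt(s2_B), sqrt(s2_W))
      }
    }
  }
  list(draws = draws, chain = chain_id, chains = chains, iter = iter,
       warmup = warmup,
       priors = list(sd_prior = sprintf("half-t(3, %.3g)", A_scale),
                     sd_prior_site_date = sprintf("half-t(3, %.3g)", A_scale_nuis),
                     beta_prior = sprintf("normal(0, %.3g)", beta_sd)))
}
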