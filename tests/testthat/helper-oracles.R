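# Independent oracles: deliberately naive implementations (loops, scalar
# densities) against which the vectorised package code is checked.

# mixture log-likelihood by brute force: loop over patients, groups, months
brute_loglik <- function(pi, beta, sigma, Y, s) {
  total <- 0
  for (i in seq_len(nrow(Y))) {
    mix <- 0
    for (g in seq_along(pi)) {
      dens <- 1
      for (t in seq_len(ncol(Y))) {
        mu <- sum(beta[[g]] * s[t]^(seq_along(beta[[g]]) - 1))
        dens <- dens * stats::dnorm(Y[i, t], mu, sigma)
      }
      mix <- mix + pi[g] * dens
    }
    total <- total + log(mix)
  }
  total
}

# death-anchored aggregation by brute force over (patient, month, category)
brute_panel <- function(claims, patients, window = 60L) {
  ids <- as.character(patients$patient_id)
  cats <- eol_categories()
  ym <- function(x) {
    as.integer(substr(x, 1, 4)) * 12L + as.integer(substr(x, 6, 7)) - 1L
  }
  death <- ym(substr(patients$death_date, 1, 7))
  arr <- array(0, dim = c(length(ids), window, length(cats)),
               dimnames = list(ids, NULL, cats))
  for (r in seq_len(nrow(claims))) {
    i <- match(as.character(claims$patient_id[r]), ids)
    m <- death[i] - ym(claims$billing_month[r]) + 1L
    if (m >= 1L && m <= window) {
      k <- match(claims$category[r], cats)
      arr[i, m, k] <- arr[i, m, k] + claims$amount_yen[r]
    }
  }
  arr
}

# random small claim sets for property tests
random_claims <- function(n_pat, n_claims, seed) {
  set.seed(seed)
  ids <- sprintf("Q%02d", seq_len(n_pat))
  death_m <- sample(0:11, n_pat, replace = TRUE)
  patients <- data.frame(
    patient_id = ids,
    death_date = sprintf("2015-%02d-10", death_m + 1L),
    stringsAsFactors = FALSE
  )
  bm <- sprintf("%04d-%02d", 2014L + (death_m + 1L - 1L) %/% 12,
                sample(1:12, n_claims, replace = TRUE))
  claims <- data.frame(
    patient_id = sample(ids, n_claims, replace = TRUE),
    billing_month = sprintf("%04d-%02d", sample(2010:2015, n_claims, TRUE),
                            sample(1:12, n_claims, TRUE)),
    category = sample(eol_categories(), n_claims, replace = TRUE),
    amount_yen = round(stats::runif(n_claims, 100, 50000), 2),
    stringsAsFactors = FALSE
  )
  list(claims = claims, patients = patients)
}

# minimal two-group flat-curve configuration used by several tests
flat_two_group_config <- function(n = 200, levels = c(12, 8), sigma = 0.5,
                                  weights = c(0.6, 0.4), seed = 1) {
  curves <- lapply(levels, function(lv) {
    b <- list(lv - log(4), lv - log(4), lv - log(4), lv - log(4))
    names(b) <- eol_categories()  # four equal shares: log total = lv
    b
  })
  sim_config(n_patients = n, weights = weights, group_curves = curves,
             sigma = sigma, zero_prob = matrix(0, 2, 4), seed = seed)
}

# gbtm-shaped object holding the true aggregate curves of a calibration, for
# tests that only need beta / pi / time (e.g. labelling). Within each
# calibration the aggregated categories share the polynomial shape and differ
# only in intercept, so the aggregate curve is one member curve plus the log
# of the summed intercept shares.
calibration_truth_fit <- function(variant = "total") {
  cfg <- default_calibration(variant)
  s <- time_grid(60L)
  G <- length(cfg$weights)
  base_cats <- if (variant == "total") eol_categories()
               else c("ltc_institutional", "ltc_home")
  beta <- lapply(seq_len(G), function(g) {
    b <- cfg$group_curves[[g]][base_cats]
    int_shift <- log(sum(exp(vapply(b, `[`, numeric(1), 1) - b[[1]][1])))
    out <- b[[1]]
    out[1] <- out[1] + int_shift
    out
  })
  structure(list(beta = beta, pi = cfg$weights, sigma = cfg$sigma,
                 groups = G, orders = lengths(beta) - 1L, time = s,
                 n_months = 60L, nobs = cfg$n_patients,
                 loglik = NA_real_, n_params = NA_integer_,
                 converged = TRUE),
            class = "gbtm")
}
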