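# Shared fixtures: all built in code at test time.

# A response row taking the best (or worst) category on every item of an
# instrument. "Best" accounts for reverse coding; for items with a
# stopped-for-other-reasons level the worst substantive category is the one
# just before it.
uniform_response <- function(instrument, which = c("best", "worst")) {
  which <- match.arg(which)
  out <- tibble::tibble(person_id = which)
  for (i in seq_len(nrow(instrument$items))) {
    it <- instrument$items[i, ]
    n_valid <- it$n_categories - as.integer(!is.na(it$stopped_other_reasons_category))
    best <- if (it$reverse_scored) n_valid else 1L
    worst <- if (it$reverse_scored) 1L else n_valid
    out[[it$code]] <- if (which == "best") as.integer(best) else as.integer(worst)
  }
  out
}

# Independent per-person ML oracle: maximize the PCM log-likelihood on a
# grid + golden-section refinement (never uses the package's Newton solver).
oracle_theta <- function(x, tau_list) {
  nll <- function(theta) {
    -sum(vapply(seq_along(tau_list), function(i) {
      if (is.na(x[i])) return(0)
      log(pcm_prob(theta, tau_list[[i]])[1, x[i] + 1])
    }, numeric(1)))
  }
  stats::optimize(nll, interval = c(-20, 20), tol = 1e-9)$minimum
}

# Direct PCM probability enumeration, written independently of pcm_prob.
oracle_pcm_prob <- function(theta, tau) {
  num <- vapply(0:length(tau), function(x) {
    exp(sum(theta - tau[seq_len(x)]))
  }, numeric(1))
  num / sum(num)
}

small_sim <- function(n = 300, n_items = 8, m = 3, seed = 1, ...) {
  simulate_responses(sim_config(
    n_persons = n, bank = sim_bank(n_items, max_score = m),
    theta_sd = 1.2, seed = seed, ...))
}
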