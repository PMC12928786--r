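# Independent per-individual Monte Carlo implementation of the
# proportional multistate lifetable, used as an oracle for the cohort
# engine. Each individual carries a 3-state disease chain (healthy /
# diseased / dead-from-disease) and a separate survival indicator under
# the residual (non-disease) hazard; the proportional structure means the
# residual hazard m_all - prevalence x case-fatality is identical in both
# arms, so survival draws are shared and the arms differ only through the
# incidence multiplier. Common random numbers keep the variance of the
# cases-averted difference near its mean, so sqrt(cases averted) is a
# sound standard-error scale.
microsim_cases_averted <- function(epi, sex, cohort_ages, n_per_cohort, years,
                                   mult_by_age_year, seed) {
  d <- epi$diseases[1]
  rates <- epi$disease_rates[epi$disease_rates$disease == d & epi$disease_rates$sex == sex, ]
  rates <- rates[order(rates$age), ]
  ac <- epi$all_cause[epi$all_cause$sex == sex, ]
  ac <- ac[order(ac$age), ]

  set.seed(seed)
  total_b <- total_s <- 0
  for (a0 in cohort_ages) {
    n <- n_per_cohort
    # shared initial disease state
    diseased_b <- diseased_s <- stats::runif(n) < rates$prevalence[a0 + 1]
    chain_dead_b <- chain_dead_s <- rep(FALSE, n)
    alive <- rep(TRUE, n) # residual-hazard survival, shared across arms
    for (t in seq_len(years) - 1) {
      age <- a0 + t
      if (age > epi$terminal_age) break
      i0 <- rates$incidence[age + 1]
      f0 <- rates$case_fatality[age + 1]
      prev0 <- rates$prevalence[age + 1]
      qi_b <- 1 - exp(-i0)
      qi_s <- 1 - exp(-i0 * mult_by_age_year(age, t))
      qf <- 1 - exp(-f0)

      u_inc <- stats::runif(n)
      healthy_b <- !diseased_b & !chain_dead_b
      healthy_s <- !diseased_s & !chain_dead_s
      new_b <- healthy_b & (u_inc < qi_b)
      new_s <- healthy_s & (u_inc < qi_s)
      total_b <- total_b + sum(alive & new_b)
      total_s <- total_s + sum(alive & new_s)

      u_f <- stats::runif(n)
      die_b <- diseased_b & (u_f < qf)
      die_s <- diseased_s & (u_f < qf)
      diseased_b <- (diseased_b | new_b) & !die_b
      diseased_s <- (diseased_s | new_s) & !die_s
      chain_dead_b <- chain_dead_b | die_b
      chain_dead_s <- chain_dead_s | die_s

      # residual non-disease hazard, identical in both arms
      m_res <- max(ac$rate[age + 1] - prev0 * f0, 0)
      alive <- alive & (stats::runif(n) >= 1 - exp(-m_res))
    }
  }
  list(baseline = total_b, scenario = total_s, averted = total_b - total_s)
}
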