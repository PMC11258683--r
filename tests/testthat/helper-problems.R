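# A fit problem whose model prediction is constant (all rates zero), giving
# full control over the residuals so the weighted MSE can be checked by hand.
constant_problem <- function(obs, times, t1, w1 = 1, w2 = 0.2, level = 5) {
  net <- build_network("template_binding")
  rates <- rate_set(net, c(k_bind = 0, k_unbind = 0))
  tr <- list(times = times, conc = obs, weights = c(ML = 1),
             initial = c(ML = level), t1 = t1, name = "hand")
  fit_problem(net, rates, list(tr), w1 = w1, w2 = w2)
}
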