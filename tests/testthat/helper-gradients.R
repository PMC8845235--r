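# numeric gradient of a scalar loss in selected actor coordinates
numeric_actor_grad <- function(actor, coords, loss_fun, h = 1e-5) {
  vapply(seq_len(nrow(coords)), function(i) {
    nm <- coords$param[i]; j <- coords$index[i]
    up <- actor; up$params[[nm]][j] <- up$params[[nm]][j] + h
    dn <- actor; dn$params[[nm]][j] <- dn$params[[nm]][j] - h
    (loss_fun(up) - loss_fun(dn)) / (2 * h)
  }, numeric(1))
}

pick_coords <- function(params, n_per = 6, seed = 3) {
  set.seed(seed)
  do.call(rbind, lapply(names(params), function(nm) {
    data.frame(param = nm,
               index = sample.int(length(params[[nm]]),
                                  min(n_per, length(params[[nm]]))))
  }))
}

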