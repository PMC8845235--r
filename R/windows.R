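# State-window construction.
#
# The observation fed to the networks at day t is the last W days of
# (daily features, rhythm one-hot, real-day mask), flattened oldest-first,
# with the admission's standardized static features appended. Days before
# admission are filled by replicating day 1 with mask 0, so t < W windows
# have exactly W blocks and the network can tell padding from data.

day_block_dim <- function(pcohort) {
  length(pcohort$feature_names) + pcohort$n_rhythm_categories + 1L
}

state_dim <- function(pcohort, W) {
  W * day_block_dim(pcohort) + ncol(pcohort$statics_std)
}

# Returns the N_days x d_state matrix of windows for every admission-day,
# in pooled row order.
build_state_matrix <- function(pcohort, W) {
  pooled <- pcohort$pooled
  B <- day_block_dim(pcohort)
  n_days <- nrow(pooled$feat)
  blocks <- cbind(pooled$feat, pooled$rhythm, 1)
  S <- matrix(0, n_days, W * B)
  offset <- 0L
  for (i in seq_along(pooled$T_len)) {
    Ti <- pooled$T_len[i]
    rows <- offset + seq_len(Ti)
    pad <- blocks[rows[1], , drop = FALSE]
    pad[, B] <- 0  # mask channel: padded day
    padded <- rbind(pad[rep(1, W - 1L), , drop = FALSE],
                    blocks[rows, , drop = FALSE])
    win_idx <- outer(seq_len(Ti), 0:(W - 1L), `+`)  # rows into padded
    arr <- padded[as.vector(t(win_idx)), , drop = FALSE]
    S[rows, ] <- matrix(as.vector(t(arr)), nrow = Ti, byrow = TRUE)
    offset <- offset + Ti
  }
  cbind(S, pcohort$statics_std[pooled$adm, , drop = FALSE])
}

# Offline transition dataset: (S_t, A_t, S_{t+1}, r_t) tuples with terminal
# flags; the next-state window of a terminal day is the zero vector
# (trajectory termination).
build_transitions <- function(pcohort, r_survive = 15, r_die = 15, W = 5L) {
  pooled <- pcohort$pooled
  S <- build_state_matrix(pcohort, W)
  n <- nrow(S)
  terminal <- pooled$day == pooled$T_len[pooled$adm]
  Snext <- matrix(0, n, ncol(S))
  Snext[!terminal, ] <- S[which(!terminal) + 1L, , drop = FALSE]
  r <- numeric(n)
  r[terminal] <- ifelse(pooled$died[pooled$adm[terminal]], -r_die, r_survive)
  list(S = S, Snext = Snext, A = pooled$actions, r = r,
       terminal = terminal,
       Didx = pcohort$diag_idx[pooled$adm, , drop = FALSE],
       adm = pooled$adm, day = pooled$day, n = n,
       died = pooled$died, T_len = pooled$T_len)
}
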