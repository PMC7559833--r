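# Shared test helpers: random panel generation and independent first-
# principles oracles the vectorised implementations are checked against.

random_panel <- function(n_experts, n_items, scale = likert_scale(1, 5)) {
  m <- matrix(
    sample(scale$lowest:scale$highest, n_experts * n_items, replace = TRUE),
    n_experts, n_items,
    dimnames = list(paste0("e", seq_len(n_experts)), paste0("q", seq_len(n_items)))
  )
  rating_matrix(m, scale)
}

# Brute-force screening oracle: plain loops straight from the rule's
# definition, no shared code with flag_deviant_answers().
brute_force_flags <- function(x, pool = expert_ids(x), d = 3, m = 2, inclusive = TRUE) {
  r <- ratings(x)
  out <- data.frame(expert_id = character(0), item_id = character(0))
  for (e in pool) {
    for (it in item_ids(x)) {
      others <- setdiff(pool, e)
      loo <- sum(r[others, it]) / length(others)
      diff <- abs(r[e, it] - loo)
      hit <- if (inclusive) diff >= d - 1e-9 else diff > d + 1e-9
      if (hit) out <- rbind(out, data.frame(expert_id = e, item_id = it))
    }
  }
  counts <- table(factor(out$expert_id, levels = pool))
  list(flags = out, excluded = pool[counts >= m])
}

# Independent V from category frequencies: V = sum(freq_c * (c - l)) / (n k).
v_from_frequencies <- function(freq, scale) {
  cats <- scale$lowest:scale$highest
  n <- sum(freq)
  sum(freq * (cats - scale$lowest)) / (n * scale$span)
}
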