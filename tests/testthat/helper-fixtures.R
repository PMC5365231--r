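# Shared fixtures and oracle helpers, built in code.

# diamond: s->a->t (1, 1) and s->b->t (2, 2); shortest path s-a-t cost 2
diamond_net <- function() {
  interaction_network(data.frame(
    tail = c("s", "a", "s", "b"), head = c("a", "t", "b", "t"),
    weight = c(1, 1, 2, 2)))
}

# probability-weight diamond: s-a-t product 0.64, s-b-t product 0.25
prob_diamond_net <- function() {
  interaction_network(data.frame(
    tail = c("s", "a", "s", "b"), head = c("a", "t", "b", "t"),
    weight = c(0.8, 0.8, 0.5, 0.5)))
}

# penalty-swap fixture: short low-score path s-a-t (0.4 * 0.4 = 0.16) vs
# long high-score path s-b-c-d-t (0.8^4 = 0.4096).  With penalty 1 the long
# path has lower cost; the ranks swap once the penalty exceeds
# exp((2*(-log 0.4) - 4*(-log 0.8)) / 2) ~= 1.600
penalty_net <- function() {
  interaction_network(data.frame(
    tail = c("s", "a", "s", "b", "c", "d"),
    head = c("a", "t", "b", "c", "d", "t"),
    weight = c(0.4, 0.4, 0.8, 0.8, 0.8, 0.8)))
}

# 3x3 layered grid: 9 equal-cost source->target paths but only 8 nodes, so a
# per-node emitter must miss at least one path
grid_net <- function() {
  mids1 <- c("a", "b", "c"); mids2 <- c("d", "e", "f")
  edges <- rbind(
    data.frame(tail = "s", head = mids1),
    expand.grid(tail = mids1, head = mids2, stringsAsFactors = FALSE),
    data.frame(tail = mids2, head = "t"))
  edges$weight <- 1
  interaction_network(edges)
}

# deterministic sweep of random instances; returns list of specs
random_instances <- function(n_instances, seed_base = 1000L) {
  modes <- c("probability", "additive", "unweighted")
  probs <- c(0.2, 0.4, 0.6)
  lapply(seq_len(n_instances), function(i) {
    list(seed = seed_base + i,
         n = 4L + (i %% 5L),                    # 4..8 nodes
         p = probs[1L + (i %% 3L)],
         mode = modes[1L + (i %% length(modes))])
  })
}

instance_network <- function(spec) {
  generate_network(spec$n, edge_probability = spec$p,
                   weight_mode = spec$mode, seed = spec$seed)
}

# origin = first node, anchor = last node: deterministic and never equal
instance_endpoints <- function(net) {
  list(origin = net$nodes[1L], anchor = net$nodes[length(net$nodes)])
}

path_ids <- function(paths) vapply(paths, function(p) paste(p$nodes, collapse = "|"),
                                   character(1))
path_costs <- function(paths) vapply(paths, `[[`, numeric(1), "cost")

# exact agreement of yen output with the oracle prefix
expect_matches_oracle <- function(yen, oracle, k) {
  expect_identical(path_ids(yen), path_ids(oracle)[seq_len(min(k, length(oracle)))])
  expect_identical(path_costs(yen),
                   path_costs(oracle)[seq_len(min(k, length(oracle)))])
}
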