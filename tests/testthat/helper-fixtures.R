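# Shared fixtures: a small synthetic reaction space (kept small so the whole
# suite runs quickly), a CSV round-trip helper, and independent oracles for
# the selection and gradient machinery.

# oracle: verify each greedy Kennard-Stone step maximizes the minimum
# distance to the already-selected set, by direct enumeration
ks_step_optimal <- function(Z, order) {
  D <- as.matrix(dist(Z))
  if (D[order[1], order[2]] != max(D)) return(FALSE)
  for (k in seq_along(order)[-(1:2)]) {
    sel <- order[seq_len(k - 1)]
    remaining <- setdiff(seq_len(nrow(Z)), sel)
    mind <- apply(D[remaining, sel, drop = FALSE], 1, min)
    if (mind[match(order[k], remaining)] < max(mind) - 1e-12) return(FALSE)
  }
  TRUE
}

# oracle: central finite differences of a scalar function of a flat
# parameter vector
fd_grad <- function(fun, theta, h = 1e-5) {
  vapply(seq_along(theta), function(i) {
    tp <- theta; tm <- theta
    tp[i] <- tp[i] + h
    tm[i] <- tm[i] - h
    (fun(tp) - fun(tm)) / (2 * h)
  }, numeric(1))
}

small_synth_config <- function(seed = 1L)
  synth_config(roles = c(aryl_halide = 6L, ligand = 3L, base = 2L,
                         additive = 8L),
               descriptor_dim = 8L, n_informative = 2L, seed = seed)

small_dataset <- local({
  cache <- new.env()
  function(seed = 1L) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]]))
      cache[[key]] <- gen_dataset(small_synth_config(seed))
    cache[[key]]
  }
})

write_toy_csvs <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(data.frame(component_id = c("a1", "a2"),
                       d1 = c(1, 4), d2 = c(2, 5), d3 = c(3, 6)),
            file.path(dir, "roleA.csv"), row.names = FALSE)
  write.csv(data.frame(component_id = c("b1", "b2"),
                       v1 = c(10, 30), v2 = c(20, 40)),
            file.path(dir, "roleB.csv"), row.names = FALSE)
  write.csv(data.frame(reaction_id = c("r1", "r2"),
                       roleA = c("a1", "a2"), roleB = c("b2", "b1"),
                       yield = c(12.5, 80)),
            file.path(dir, "reactions.csv"), row.names = FALSE)
  list(reactions = file.path(dir, "reactions.csv"),
       descriptors = list(roleA = file.path(dir, "roleA.csv"),
                          roleB = file.path(dir, "roleB.csv")))
}
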