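# independent oracle for the hydrostatic (no-solute) case: the root is an
# electrical-analogue resistor network. Built here as a dense Laplacian over
# an explicit edge list and solved with base R solve(), a code path fully
# separate from the package's tree elimination.
oracle_hydrostatic <- function(g, params, bath) {
  nodes <- g$nodes
  n <- nrow(nodes)
  pos <- integer(max(nodes$rev_id))
  pos[nodes$rev_id] <- seq_len(n)
  K_ref <- axial_conductance_at(nodes$dist_tip, params)
  ge <- K_ref / nodes$length

  # node indices: 1..n REVs; n+1 bath (potential Pe); n+2 ground (P = 0)
  edges <- data.frame(a = integer(0), b = integer(0), g = numeric(0))
  add_edge <- function(a, b, gcond) {
    edges[nrow(edges) + 1L, ] <<- list(a, b, gcond)
  }
  for (i in seq_len(n)) {
    add_edge(i, n + 1L, params$k * nodes$surface[i])      # radial path
    if (is.na(nodes$parent[i])) {
      add_edge(i, n + 2L, ge[i])                          # basal face
    } else {
      add_edge(i, pos[nodes$parent[i]], ge[i])            # axial edge
    }
    if (nodes$is_cut_face[i]) add_edge(i, n + 1L, ge[i])  # open cut face
  }
  N <- n + 2L
  L <- matrix(0, N, N)
  for (e in seq_len(nrow(edges))) {
    a <- edges$a[e]; b <- edges$b[e]; gc <- edges$g[e]
    L[a, a] <- L[a, a] + gc
    L[b, b] <- L[b, b] + gc
    L[a, b] <- L[a, b] - gc
    L[b, a] <- L[b, a] - gc
  }
  # Dirichlet: bath node at Pe, ground at 0; solve for interior potentials
  rhs <- -L[seq_len(n), n + 1L] * bath$Pe
  P <- solve(L[seq_len(n), seq_len(n)], rhs)
  basal <- which(is.na(nodes$parent))
  list(P = P, Jv = ge[basal] * P[basal])
}
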