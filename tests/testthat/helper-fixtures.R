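# Shared helpers: small geometries and independent oracles built in code.

# A two-box mesh: slab of thickness 2 split into two tagged volumes at
# z = 1, with the interface triangles tagged 9.  Face matching below is an
# independent brute-force oracle, not the package's internal path.
make_two_box <- function(n = 2) {
  m <- generate_slab(1, 1, 2, n)
  zc <- (m$vertices[m$cells[, 1], 3] + m$vertices[m$cells[, 2], 3] +
         m$vertices[m$cells[, 3], 3] + m$vertices[m$cells[, 4], 3]) / 4
  tags <- ifelse(zc < 1, 1L, 2L)
  # brute force: every face of every cell, keyed by sorted vertex triple
  faces <- list(); owner <- integer(0)
  for (c_i in seq_len(nrow(m$cells))) {
    vs <- m$cells[c_i, ]
    for (drop in 1:4) {
      faces[[length(faces) + 1L]] <- sort(vs[-drop])
      owner <- c(owner, c_i)
    }
  }
  keys <- vapply(faces, paste, "", collapse = "_")
  tab <- split(seq_along(keys), keys)
  inter <- list()
  for (idx in tab) {
    if (length(idx) == 2L && tags[owner[idx[1]]] != tags[owner[idx[2]]]) {
      inter[[length(inter) + 1L]] <- faces[[idx[1]]]
    }
  }
  inter <- do.call(rbind, inter)
  parent_mesh(m$vertices, m$cells, tags,
              facets = rbind(m$facets, inter),
              facet_tags = c(m$facet_tags, rep(9L, nrow(inter))),
              facet_tag_names = list(`2` = "membrane", `3` = "no_flux",
                                     `9` = "interface"))
}

# finite-difference Jacobian check of the assembled reaction terms against
# the symbolic path, at a randomized positive state
fd_jacobian_error <- function(model, nprobe = 15, seed = 1) {
  set.seed(seed)
  sys <- rdmix:::build_system(model)
  u <- rdmix:::model_initial_state(model) + runif(sys$dof$total, 0.1, 0.6)
  ps <- list()
  for (pm in model$parameters) {
    if (pm$kind %in% c("constant", "prestep")) ps[[pm$name]] <- pm$value
  }
  r0 <- rdmix:::assemble_reaction(sys, u, 0.25, ps)
  J <- Matrix::sparseMatrix(i = unlist(r0$jac$i), j = unlist(r0$jac$j),
                            x = unlist(r0$jac$x),
                            dims = rep(sys$dof$total, 2))
  relmax <- 0
  for (k in sample(sys$dof$total, min(nprobe, sys$dof$total))) {
    h <- 1e-6 * max(abs(u[k]), 1)
    up <- u; up[k] <- u[k] + h
    um <- u; um[k] <- u[k] - h
    fd <- (rdmix:::assemble_reaction(sys, up, 0.25, ps)$load -
           rdmix:::assemble_reaction(sys, um, 0.25, ps)$load) / (2 * h)
    col <- as.numeric(J[, k])
    denom <- max(max(abs(col)), 1e-12)
    relmax <- max(relmax, max(abs(fd - col)) / denom)
  }
  relmax
}

# independent 1D finite-difference boundary-value oracle for the slab
# steady state: D u'' = kp u on (0, L), -D u'(0) = kkin (Atot - u(0)),
# u'(L) = 0, solved on a fine grid with a tridiagonal direct solve
slab_bvp_oracle <- function(problem, N = 20000) {
  L <- problem$L; D <- problem$D; kk <- problem$k_kin
  kp <- problem$k_p; At <- problem$A_tot
  h <- L / N
  z <- seq(0, L, length.out = N + 1)
  main <- rep(-2 * D / h^2 - kp, N + 1)
  lower <- rep(D / h^2, N)   # lower[i] multiplies u[i] in row i+1
  upper <- rep(D / h^2, N)   # upper[i] multiplies u[i+1] in row i
  rhs <- rep(0, N + 1)
  # ghost-node Robin at z = 0:  D (u1 - u_{-1}) / (2h) = -kkin (At - u0)
  upper[1] <- 2 * D / h^2
  main[1] <- -2 * D / h^2 - kp - 2 * kk / h
  rhs[1] <- -2 * kk * At / h
  # no-flux at z = L
  lower[N] <- 2 * D / h^2
  # Thomas algorithm
  n <- N + 1
  cp <- numeric(n); dp <- numeric(n)
  cp[1] <- upper[1] / main[1]
  dp[1] <- rhs[1] / main[1]
  for (i in 2:n) {
    denom <- main[i] - lower[i - 1] * cp[i - 1]
    cp[i] <- if (i < n) upper[i] / denom else 0
    dp[i] <- (rhs[i] - lower[i - 1] * dp[i - 1]) / denom
  }
  u <- numeric(n)
  u[n] <- dp[n]
  for (i in (n - 1):1) u[i] <- dp[i] - cp[i] * u[i + 1]
  list(z = z, u = u)
}

run_and_totals <- function(model, t_final, dt, nout = 100) {
  s <- run_simulation(model, t_final = t_final, dt = dt,
                      output_times = seq(t_final / nout, t_final,
                                         length.out = nout))
  tots <- vapply(seq_along(s$times), function(k) {
    total_amount(s, time = s$times[k])
  }, 1)
  list(series = s, totals = tots)
}
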