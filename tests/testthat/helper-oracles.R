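# Independent oracles, coded separately from the package internals.

# --- dense-assembly solid oracle -------------------------------------------
# Plain-R implementation of the same discrete functional (after exact
# elimination of the nodal pressure, p_a = kappa_a (Jbar_a - 1)):
#   Pi(u) = sum_e V0e C1 (J^-2/3 I1 - 3)            (deviatoric)
#         + sum_a V0a kbar_a/2 (Jbar_a - 1)^2       (nodal volumetric)
#         + sum_e V0e kloc_e/2 (J_e - 1)^2          (local stabilization)
#         - f . u
# with an analytic gradient and finite-difference Hessian; dense Newton.

dense_elem_geom <- function(X) {
  Dm <- cbind(X[2, ] - X[1, ], X[3, ] - X[1, ], X[4, ] - X[1, ])
  V0 <- det(Dm) / 6
  Bm <- solve(Dm)
  G <- rbind(-colSums(Bm), Bm)    # 4 x 3 shape gradients
  list(V0 = V0, G = G)
}

dense_energy_grad <- function(nodes, elems, u, C1, kap, kloc, nodal) {
  nn <- nrow(nodes)
  grad <- matrix(0, nn, 3)
  geom <- lapply(seq_len(nrow(elems)),
                 function(e) dense_elem_geom(nodes[elems[e, ], ]))
  Fs <- vector("list", nrow(elems))
  Js <- numeric(nrow(elems))
  nodeV <- numeric(nn); nodeJV <- numeric(nn); nodeK <- numeric(nn)
  for (e in seq_len(nrow(elems))) {
    g <- geom[[e]]
    Fm <- diag(3)
    for (i in 1:4) Fm <- Fm + tcrossprod(u[elems[e, i], ], g$G[i, ])
    Fs[[e]] <- Fm
    Js[e] <- det(Fm)
    if (nodal[e]) {
      w <- g$V0 / 4
      for (i in 1:4) {
        a <- elems[e, i]
        nodeV[a] <- nodeV[a] + w
        nodeJV[a] <- nodeJV[a] + w * Js[e]
        nodeK[a] <- nodeK[a] + w * kap[e]
      }
    }
  }
  Jbar <- ifelse(nodeV > 0, nodeJV / nodeV, 1)
  kbar <- ifelse(nodeV > 0, nodeK / pmax(nodeV, 1e-300), 0)
  energy <- sum(ifelse(nodeV > 0, nodeV * kbar / 2 * (Jbar - 1)^2, 0))
  for (e in seq_len(nrow(elems))) {
    g <- geom[[e]]
    Fm <- Fs[[e]]; J <- Js[e]
    I1 <- sum(Fm^2)
    aT <- t(solve(Fm))
    energy <- energy + g$V0 * C1[e] * (J^(-2 / 3) * I1 - 3)
    Pdev <- 2 * C1[e] * J^(-2 / 3) * (Fm - (I1 / 3) * aT)
    if (nodal[e]) {
      pe <- kloc[e] * (J - 1) + mean(kbar[elems[e, ]] * (Jbar[elems[e, ]] - 1))
      energy <- energy + g$V0 * kloc[e] / 2 * (J - 1)^2
    } else {
      pe <- kap[e] * (J - 1)
      energy <- energy + g$V0 * kap[e] / 2 * (J - 1)^2
    }
    P <- Pdev + pe * J * aT
    for (i in 1:4)
      grad[elems[e, i], ] <- grad[elems[e, i], ] + g$V0 * as.numeric(P %*% g$G[i, ])
  }
  list(energy = energy, grad = grad)
}

# Dense Newton on the free dofs (FD Hessian of the analytic gradient).
dense_newton_solve <- function(nodes, elems, C1, kap, kloc, nodal,
                               f_nodal, free, n_steps = 5, tol = 1e-12) {
  nn <- nrow(nodes)
  u <- matrix(0, nn, 3)
  uvec <- function(u) as.vector(t(u))[free]
  to_mat <- function(v) {
    full <- numeric(3 * nn); full[free] <- v
    matrix(full, nn, 3, byrow = TRUE)
  }
  fv <- as.vector(t(f_nodal))[free]
  for (s in seq_len(n_steps)) {
    lam <- s / n_steps
    for (it in 1:60) {
      eg <- dense_energy_grad(nodes, elems, u, C1, kap, kloc, nodal)
      r <- as.vector(t(eg$grad))[free] - lam * fv
      if (sqrt(sum(r^2)) < tol * max(1, lam * sqrt(sum(fv^2)))) break
      nfree <- length(free)
      H <- matrix(0, nfree, nfree)
      hstep <- 1e-7
      for (j in seq_len(nfree)) {
        dv <- numeric(nfree); dv[j] <- hstep
        gp <- dense_energy_grad(nodes, elems, u + to_mat(dv), C1, kap,
                                kloc, nodal)$grad
        gm <- dense_energy_grad(nodes, elems, u - to_mat(dv), C1, kap,
                                kloc, nodal)$grad
        H[, j] <- (as.vector(t(gp))[free] - as.vector(t(gm))[free]) /
          (2 * hstep)
      }
      H <- (H + t(H)) / 2
      du <- solve(H, -r)
      u <- u + to_mat(du)
    }
  }
  u
}

# --- chi-square permutation oracle -----------------------------------------
# Monte-Carlo p-value under fixed margins, with the Pearson statistic
# computed from first principles.
chisq_stat_manual <- function(m) {
  E <- outer(rowSums(m), colSums(m)) / sum(m)
  sum((m - E)^2 / E)
}

chisq_perm_p <- function(m, n_draws = 1e5, seed = 1) {
  set.seed(seed)
  obs <- chisq_stat_manual(m)
  draws <- r2dtable(n_draws, rowSums(m), colSums(m))
  stats <- vapply(draws, chisq_stat_manual, numeric(1))
  mean(stats >= obs - 1e-12)
}
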