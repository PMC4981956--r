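# Fixture builders and independent oracles used across the suite.

make_specimen <- function(taxon_id = "sp1", status = "extant",
                          L_axis1 = 100, L_axis2 = 10, head_length = 12,
                          L_head_in_vertebrae = 5, N_PCV = 50, N_CV = 60,
                          AR_head = 2, AR_PCV = 3, AR_CV = 2.5,
                          clade = NA_character_) {
  data.frame(taxon_id = taxon_id, status = status, clade = clade,
             L_axis1 = L_axis1, L_axis2 = L_axis2,
             head_length = head_length,
             L_head_in_vertebrae = L_head_in_vertebrae,
             N_PCV = N_PCV, N_CV = N_CV, AR_head = AR_head,
             AR_PCV = AR_PCV, AR_CV = AR_CV,
             stringsAsFactors = FALSE)
}

random_specimens <- function(n, seed = 1) {
  set.seed(seed)
  l1 <- runif(n, 100, 1000)
  make_specimen(taxon_id = sprintf("sp%03d", seq_len(n)),
                status = sample(c("extinct", "extant"), n, replace = TRUE),
                L_axis1 = l1, L_axis2 = l1 / runif(n, 5, 30),
                head_length = l1 * runif(n, 0.05, 0.15),
                L_head_in_vertebrae = runif(n, 2, 10),
                N_PCV = sample(30:80, n, replace = TRUE),
                N_CV = sample(40:120, n, replace = TRUE),
                AR_head = runif(n, 0.5, 3),
                AR_PCV = runif(n, 0.5, 2.5),
                AR_CV = runif(n, 0.5, 2.5))
}

make_tendon_obs <- function(taxon_id = "fossil1", element = "ENB",
                            side = "epaxial", k_min = 1, k_max = k_min,
                            tl_start = 60, tl_end = 95) {
  data.frame(taxon_id = taxon_id, element = element, side = side,
             k_min = k_min, k_max = k_max, tl_start = tl_start,
             tl_end = tl_end, element_length = NA_real_,
             stringsAsFactors = FALSE)
}

# star tree with all tips at depth t, dated
star_tree <- function(n, depth = 1) {
  phy <- ape::stree(n, type = "star")
  age <- c(rep(0, n), depth)
  anguimorph:::.as_dated(phy, age)
}

# ORACLE: tips x tips shared path length from the root, by explicit
# enumeration of each tip's root path and summation of shared edge
# durations (independent of the MRCA-based implementation)
path_sum_covariance <- function(phy) {
  age <- anguimorph::node_ages(phy)
  ntip <- ape::Ntip(phy)
  root <- ntip + 1L
  parent_of <- integer(ntip + phy$Nnode)
  parent_of[phy$edge[, 2]] <- phy$edge[, 1]
  root_path <- function(i) {        # edges as child node ids, tipward
    out <- integer(0)
    while (i != root) { out <- c(out, i); i <- parent_of[i] }
    out
  }
  paths <- lapply(seq_len(ntip), root_path)
  C <- matrix(0, ntip, ntip)
  for (i in seq_len(ntip)) for (j in seq_len(ntip)) {
    shared <- intersect(paths[[i]], paths[[j]])
    C[i, j] <- sum(age[parent_of[shared]] - age[shared])
  }
  dimnames(C) <- list(phy$tip.label, phy$tip.label)
  C
}

# ORACLE: ray-casting point-in-convex-polygon test (vertex order free);
# independent of the half-plane production code
ray_cast_inside <- function(p, pts, tol = 1e-9) {
  h <- grDevices::chull(pts)
  poly <- pts[h, , drop = FALSE]
  m <- nrow(poly)
  # boundary check first (distance to each segment)
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    ab <- b - a
    t <- sum((p - a) * ab) / max(sum(ab^2), .Machine$double.eps)
    t <- min(max(t, 0), 1)
    if (sqrt(sum((p - (a + t * ab))^2)) < tol) return(TRUE)
  }
  crossings <- 0L
  for (i in seq_len(m)) {
    a <- poly[i, ]; b <- poly[if (i == m) 1 else i + 1, ]
    if ((a[2] > p[2]) != (b[2] > p[2])) {
      xint <- a[1] + (p[2] - a[2]) * (b[1] - a[1]) / (b[2] - a[2])
      if (p[1] < xint) crossings <- crossings + 1L
    }
  }
  crossings %% 2L == 1L
}

# ORACLE: squared-change parsimony by iterated exhaustive 1-D grid
# minimisation per internal node (the objective is convex, so coordinate
# descent over exhaustive grids reaches the global optimum)
grid_asr <- function(phy, trait, step = 1e-3, sweeps = 60) {
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  x <- numeric(nn)
  x[seq_len(ntip)] <- trait[phy$tip.label]
  rng <- range(trait)
  grid <- seq(rng[1], rng[2], by = step)
  internal <- (ntip + 1L):nn
  x[internal] <- mean(rng)
  cost <- function(x) sum((x[phy$edge[, 1]] - x[phy$edge[, 2]])^2)
  for (s in seq_len(sweeps)) {
    old <- x[internal]
    for (v in internal) {
      nb <- c(x[phy$edge[phy$edge[, 1] == v, 2]],
              x[phy$edge[phy$edge[, 2] == v, 1]])
      # per-coordinate objective is sum((z - nb)^2): exhaustive 1-D grid
      z <- grid[which.min(vapply(grid,
                                 function(g) sum((g - nb)^2), 0))]
      x[v] <- z
    }
    if (max(abs(x[internal] - old)) < step / 2) break
  }
  list(ace = x[internal], cost = cost(x))
}

composite_fixture <- function() {
  ext <- function(f) system.file("extdata", f, package = "anguimorph")
  list(tree = read_tree(ext("composite_tree.nwk")),
       tip_ages = read_tip_ages(ext("composite_tip_ages.csv")),
       constraints = read_constraints(ext("composite_constraints.csv")),
       tendons = read_tendon_table(ext("fossil_tendons.csv")))
}
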