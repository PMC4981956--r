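#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the generator.  The defaults encode the group
#' structure the analyses assume: extinct taxa have fewer vertebrae with
#' relatively longer (higher aspect-ratio) centra than extant ones, with
#' the group means separated by \code{group_offset_sd} pooled standard
#' deviations on the vertebral-count and centrum-aspect-ratio variables
#' (default 3; 0 gives a null configuration with identical groups, and
#' the sign of the offset may be flipped via a negative value).  Explicit
#' per-group means/SDs override the offset construction.
#'
#' @param seed integer root seed; per-stage substreams are derived from it
#'   by fixed offsets so stages can be re-run in isolation.
#' @param n_extinct,n_extant group sizes (>= 3 each).
#' @param group_offset_sd separation of the group means in pooled SDs.
#' @param pcv_base,pcv_sd,cv_base,cv_sd base mean and SD of the precaudal
#'   and caudal vertebral counts.
#' @param ar_base,ar_sd base mean and SD of the centrum aspect ratio
#'   (length/height).
#' @param length_meanlog,length_sdlog log-normal parameters of standard
#'   length in mm.
#' @param min_total_vertebrae resampling floor on the total vertebral
#'   count (anguilliform realism).
#' @param tree_n_tips,birth_rate Yule-tree parameters.
#' @param bm_sigma2,root_state,lambda_true Brownian-trait parameters.
#' @return a \code{simulation_config} list.
#' @export
simulation_config <- function(seed = 1L,
                              n_extinct = 12L, n_extant = 15L,
                              group_offset_sd = 3,
                              pcv_base = 52, pcv_sd = 6,
                              cv_base = 80, cv_sd = 10,
                              ar_base = 1.2, ar_sd = 0.15,
                              length_meanlog = log(400),
                              length_sdlog = 0.4,
                              min_total_vertebrae = 40L,
                              tree_n_tips = 32L, birth_rate = 1,
                              bm_sigma2 = 1, root_state = 0,
                              lambda_true = 1) {
  stopifnot(n_extinct >= 3, n_extant >= 3, pcv_sd > 0, cv_sd > 0,
            ar_sd > 0, length_sdlog > 0, tree_n_tips >= 2,
            birth_rate > 0, bm_sigma2 > 0,
            lambda_true >= 0, lambda_true <= 1)
  d <- group_offset_sd / 2
  cfg <- list(
    seed = as.integer(seed),
    n_extinct = as.integer(n_extinct), n_extant = as.integer(n_extant),
    ## extant: more vertebrae; extinct: relatively longer centra
    pcv_mean = c(extinct = pcv_base - d * pcv_sd,
                 extant = pcv_base + d * pcv_sd),
    pcv_sd = c(extinct = pcv_sd, extant = pcv_sd),
    cv_mean = c(extinct = cv_base - d * cv_sd,
                extant = cv_base + d * cv_sd),
    cv_sd = c(extinct = cv_sd, extant = cv_sd),
    ar_mean = c(extinct = ar_base + d * ar_sd,
                extant = ar_base - d * ar_sd),
    ar_sd = c(extinct = ar_sd, extant = ar_sd),
    length_meanlog = length_meanlog, length_sdlog = length_sdlog,
    min_total_vertebrae = as.integer(min_total_vertebrae),
    tree_n_tips = as.integer(tree_n_tips), birth_rate = birth_rate,
    bm_sigma2 = bm_sigma2, root_state = root_state,
    lambda_true = lambda_true,
    group_offset_sd = group_offset_sd)
  if (any(cfg$ar_mean <= 0))
    stop("infeasible config: non-positive centrum aspect-ratio mean",
         call. = FALSE)
  class(cfg) <- "simulation_config"
  cfg
}

## fixed per-stage seed substreams derived from one root seed
.stage_seed <- function(cfg, stage) {
  offsets <- c(tree = 101L, trait = 211L, specimens = 307L,
               tendons = 401L)
  (cfg$seed + offsets[[stage]]) %% .Machine$integer.max
}

#' Simulate a Yule (pure-birth) tree
#'
#' Starts from the root with two lineages; with k extant lineages the
#' waiting time to the next speciation is exponential with rate k times
#' the birth rate, and a uniformly chosen lineage splits.  After the nth
#' lineage appears the process is observed one further (memoryless)
#' exponential waiting time later, so the expected root age is
#' \eqn{\sum_{k=2}^{n} 1/(k\,b)}.  The tree is ultrametric with extant
#' tips at age 0.
#'
#' @param n_tips number of tips (>= 2).
#' @param birth_rate speciation rate b (> 0), per Ma.
#' @param seed optional integer seed; identical seeds give identical
#'   trees.
#' @return a \code{dated_phylo} with tip labels \code{t1..tn}.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  stopifnot(n_tips >= 2, birth_rate > 0)
  if (!is.null(seed)) set.seed(seed)
  n_tips <- as.integer(n_tips)
  nnode <- n_tips - 1L
  root <- n_tips + 1L
  next_internal <- root + 1L
  ## active lineages: parent internal node and branch start time
  act_par <- c(root, root)
  act_t0 <- c(0, 0)
  edges <- matrix(0L, 0, 2)
  e_start <- e_end <- numeric(0)
  node_time <- numeric(n_tips + nnode)
  node_time[root] <- 0
  t <- 0
  for (k in 2:n_tips) {
    t <- t + stats::rexp(1, rate = k * birth_rate)
    if (k == n_tips) break
    i <- sample.int(length(act_par), 1L)
    new <- next_internal; next_internal <- next_internal + 1L
    edges <- rbind(edges, c(act_par[i], new))
    e_start <- c(e_start, act_t0[i]); e_end <- c(e_end, t)
    node_time[new] <- t
    act_par <- c(act_par[-i], new, new)
    act_t0 <- c(act_t0[-i], t, t)
  }
  total <- t
  for (i in seq_along(act_par)) {
    edges <- rbind(edges, c(act_par[i], i))
    e_start <- c(e_start, act_t0[i]); e_end <- c(e_end, total)
    node_time[i] <- total
  }
  storage.mode(edges) <- "integer"
  phy <- list(edge = edges,
              edge.length = e_end - e_start,
              tip.label = paste0("t", seq_len(n_tips)),
              Nnode = nnode)
  class(phy) <- "phylo"
  phy <- ape::reorder.phylo(phy, "cladewise")
  age <- total - node_time
  age[seq_len(n_tips)] <- 0
  .as_dated(phy, age)
}

#' Simulate a Brownian-motion trait on a dated tree
#'
#' Draws tip values from a multivariate normal with mean
#' \code{root_state} and covariance \code{sigma2 * C(lambda_true)}, where
#' C is the Brownian covariance of the tree and the lambda transform
#' scales its off-diagonal entries; \code{lambda_true = 1} is plain
#' Brownian motion and \code{lambda_true = 0} gives independent tips.
#'
#' @param phy a \code{dated_phylo}.
#' @param sigma2 Brownian rate (> 0), trait variance per Ma.
#' @param root_state trait value at the root.
#' @param lambda_true signal strength in \[0, 1\].
#' @param seed optional integer seed.
#' @return named numeric vector of tip values.
#' @export
simulate_bm_trait <- function(phy, sigma2 = 1, root_state = 0,
                              lambda_true = 1, seed = NULL) {
  stopifnot(sigma2 > 0, lambda_true >= 0, lambda_true <= 1)
  if (!is.null(seed)) set.seed(seed)
  C <- .lambda_transform(bm_covariance(phy), lambda_true)
  R <- .chol_safe(sigma2 * C)
  x <- root_state + drop(t(R) %*% stats::rnorm(nrow(C)))
  names(x) <- phy$tip.label
  x
}

#' Generate a synthetic specimen table with group structure
#'
#' Draws, per taxon, vertebral counts (rounded normals, resampled below
#' the configured floor with a message), per-vertebra centrum lengths and
#' heights whose aspect ratios follow the group means, a log-normal
#' standard length, and the derived head fields, so that every specimen
#' invariant holds by construction.  The specimen-level aspect-ratio
#' columns are computed from the generated centra with the same
#' three-vertebra selection rule the analysis uses.
#'
#' @param cfg a [simulation_config()].
#' @return list with \code{specimens} (a \code{specimen_table}) and
#'   \code{vertebrae} (a \code{vertebra_table}).
#' @export
generate_specimen_table <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(.stage_seed(cfg, "specimens"))
  groups <- c(rep("extinct", cfg$n_extinct), rep("extant", cfg$n_extant))
  ids <- sprintf("%s_%02d", groups, stats::ave(seq_along(groups),
                                               groups, FUN = seq_along))
  specs <- vector("list", length(groups))
  verts <- vector("list", length(groups))
  n_draws <- 0L; n_bad <- 0L; n_trunc <- 0L
  for (i in seq_along(groups)) {
    g <- groups[i]
    repeat {
      n_draws <- n_draws + 1L
      n_pcv <- round(stats::rnorm(1, cfg$pcv_mean[g], cfg$pcv_sd[g]))
      n_cv <- round(stats::rnorm(1, cfg$cv_mean[g], cfg$cv_sd[g]))
      if (n_pcv < 1 || n_cv < 1) { n_bad <- n_bad + 1L; next }
      if (n_pcv + n_cv < cfg$min_total_vertebrae) {
        n_trunc <- n_trunc + 1L; next
      }
      break
    }
    if (n_bad > 0 && n_bad > 0.01 * n_draws && n_draws > 100)
      stop("infeasible config: negative vertebral counts in > 1% of draws",
           call. = FALSE)
    l1 <- stats::rlnorm(1, cfg$length_meanlog, cfg$length_sdlog)
    ## elongation (L1/L2) kept group-neutral; group contrast is carried
    ## by counts and centrum aspect ratios
    elong <- max(1.05, stats::rnorm(1, 15, 3))
    l2 <- l1 / elong
    head_len <- l1 * stats::runif(1, 0.08, 0.14)
    head_depth <- l2 * stats::runif(1, 0.6, 0.95)
    ## centra: heights vary smoothly, lengths follow the group AR
    n_tot <- n_pcv + n_cv
    height <- (l2 * 0.35) * exp(stats::rnorm(n_tot, 0, 0.05))
    ar <- pmax(0.2, stats::rnorm(n_tot, cfg$ar_mean[g], cfg$ar_sd[g]))
    len <- ar * height
    verts[[i]] <- data.frame(
      taxon_id = ids[i], index = seq_len(n_tot),
      region = rep(c("precaudal", "caudal"), c(n_pcv, n_cv)),
      centrum_length = len, centrum_height = height)
    mean_pcv_len <- mean(len[seq_len(n_pcv)])
    specs[[i]] <- data.frame(
      taxon_id = ids[i], status = g,
      clade = if (g == "extinct") "stem" else "crown",
      L_axis1 = l1, L_axis2 = l2, head_length = head_len,
      L_head_in_vertebrae = head_len / mean_pcv_len,
      N_PCV = n_pcv, N_CV = n_cv,
      AR_head = head_len / head_depth,
      AR_PCV = NA_real_, AR_CV = NA_real_)
  }
  if (n_trunc > 0)
    message(n_trunc, " draw(s) resampled below the ",
            cfg$min_total_vertebrae, "-vertebra floor")
  specimens <- do.call(rbind, specs)
  vertebrae <- validate_vertebrae(do.call(rbind, verts))
  specimens <- fill_aspect_ratios(specimens, vertebrae)
  specimens <- validate_specimens(specimens)
  list(specimens = specimens, vertebrae = vertebrae)
}

#' Generate synthetic tendon observations
#'
#' One epaxial ENB and one hypaxial EPB observation per taxon with the
#' requested traversal counts; percent-total-length extents are drawn
#' uniformly within the configured window.
#'
#' @param taxa character vector of taxon ids (may be empty).
#' @param k_values traversal counts beyond vertebra N, recycled across
#'   taxa; either a numeric vector (k_min = k_max) or a two-column matrix
#'   of ranges.
#' @param seed optional integer seed.
#' @param tl_window numeric pair: window (\% of total length) within which
#'   element extents are drawn.
#' @return a \code{tendon_table} with two rows per taxon.
#' @export
generate_tendon_observations <- function(taxa, k_values, seed = NULL,
                                         tl_window = c(55, 97)) {
  if (!length(taxa)) {
    out <- data.frame(taxon_id = character(), element = character(),
                      side = character(), k_min = numeric(),
                      k_max = numeric(), tl_start = numeric(),
                      tl_end = numeric(), element_length = numeric())
    return(validate_tendons(out))
  }
  if (!is.null(seed)) set.seed(seed)
  if (is.null(dim(k_values)))
    k_values <- cbind(k_values, k_values)
  k <- k_values[rep_len(seq_len(nrow(k_values)), length(taxa)), ,
                drop = FALSE]
  rows <- lapply(seq_along(taxa), function(i) {
    ext <- sort(stats::runif(2, tl_window[1], tl_window[2]))
    data.frame(taxon_id = taxa[i],
               element = c("ENB", "EPB"),
               side = c("epaxial", "hypaxial"),
               k_min = unname(k[i, 1]), k_max = unname(k[i, 2]),
               tl_start = ext[1], tl_end = ext[2],
               element_length = NA_real_)
  })
  validate_tendons(do.call(rbind, rows))
}

#' Run the whole synthetic pipeline
#'
#' Simulates a specimen table, computes the shape index, builds the
#' morphospace with overlap detection, simulates a Yule tree with a
#' Brownian trait, estimates phylogenetic signal and reconstructs
#' ancestral states — a smoke test of every stage, and the programmatic
#' equivalent of a run-everything command.
#'
#' @param cfg a [simulation_config()].
#' @param n_permutations permutations for the K test (kept small here).
#' @return list with the stage outputs: \code{specimens},
#'   \code{vertebrae}, \code{vsi}, \code{pca}, \code{overlap},
#'   \code{tree}, \code{trait}, \code{k}, \code{lambda}, \code{asr}.
#' @export
run_pipeline <- function(cfg = simulation_config(),
                         n_permutations = 99) {
  sim <- generate_specimen_table(cfg)
  vsi <- compute_vsi(sim$specimens)
  pca <- run_pca(sim$specimens)
  groups <- stats::setNames(sim$specimens$status, sim$specimens$taxon_id)
  overlap <- morphospace_overlap(pca, groups)
  tree <- simulate_yule_tree(cfg$tree_n_tips, cfg$birth_rate,
                             seed = .stage_seed(cfg, "tree"))
  trait <- simulate_bm_trait(tree, cfg$bm_sigma2, cfg$root_state,
                             cfg$lambda_true,
                             seed = .stage_seed(cfg, "trait"))
  k <- blomberg_k(tree, trait, n_permutations = n_permutations,
                  seed = .stage_seed(cfg, "trait"))
  lam <- pagel_lambda(tree, trait)
  asr <- parsimony_asr(tree, trait)
  list(specimens = sim$specimens, vertebrae = sim$vertebrae, vsi = vsi,
       pca = pca, overlap = overlap, tree = tree, trait = trait,
       k = k, lambda = lam, asr = asr)
}

#' Write a complete synthetic fixture directory
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created if needed).
#' @return the directory path, invisibly.
#' @export
write_fixture_dir <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- generate_specimen_table(cfg)
  write_specimen_table(sim$specimens, file.path(dir, "specimens.csv"))
  utils::write.csv(sim$vertebrae, file.path(dir, "vertebrae.csv"),
                   row.names = FALSE, quote = FALSE)
  tend <- generate_tendon_observations(
    sim$specimens$taxon_id[sim$specimens$status == "extinct"],
    k_values = c(1, 2, 2.5), seed = .stage_seed(cfg, "tendons"))
  utils::write.csv(tend, file.path(dir, "tendons.csv"),
                   row.names = FALSE, quote = FALSE, na = "")
  tree <- simulate_yule_tree(cfg$tree_n_tips, cfg$birth_rate,
                             seed = .stage_seed(cfg, "tree"))
  write_tree(tree, file.path(dir, "tree.nwk"))
  utils::write.csv(
    data.frame(taxon = tree$tip.label, first_occurrence = 0,
               last_occurrence = 0),
    file.path(dir, "tip_ages.csv"), row.names = FALSE, quote = FALSE)
  root_age <- node_ages(tree)[ape::Ntip(tree) + 1L]
  utils::write.csv(
    data.frame(mrca_of = paste(tree$tip.label, collapse = ";"),
               age = round(root_age, 1), kind = "fixed"),
    file.path(dir, "constraints.csv"), row.names = FALSE, quote = FALSE)
  flat <- cfg[vapply(cfg, function(v) length(v) == 1 && is.atomic(v),
                     TRUE)]
  writeLines(paste0(names(flat), ": ", unlist(flat)),
             file.path(dir, "config.yaml"))
  invisible(dir)
}
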