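#' Time-calibrate a composite tree from tip occurrences and node constraints
#'
#' Assigns an age (Ma before present) to every node of a rooted topology,
#' the way composite fossil + extant trees are dated by hand: constrained
#' nodes take their constraint age (kind \code{fixed}) or the maximum of
#' the constraint and the oldest first occurrence among their descendants
#' (kind \code{minimum}); every other internal node is interpolated,
#' root-to-tips, as the mean of its nearest dated ancestor and its oldest
#' dated descendant (the mean between the two bracketing estimates).
#' Terminal branches extend to each tip's first occurrence, so a branch
#' duration of parent age minus first occurrence automatically includes
#' any ghost lineage.  Conflicts (a node not strictly older than a child)
#' are raised as errors, never silently adjusted.
#'
#' @param phy a rooted \code{phylo} topology; polytomies allowed.
#' @param tip_ages data frame with \code{taxon}, \code{first_occurrence},
#'   \code{last_occurrence} (Ma; 0/0 for extant tips) covering every tip.
#' @param constraints data frame with \code{mrca_of} (list or
#'   \code{";"}-separated character of tip labels), \code{age} (Ma) and
#'   \code{kind} (\code{fixed}/\code{minimum}); must date the root.
#' @return a \code{dated_phylo}: the topology with \code{node.age} set and
#'   \code{edge.length} recomputed as parent age minus child age.
#' @examples
#' phy <- ape::read.tree(text = "((A,B),(C,D));")
#' tips <- data.frame(taxon = c("A", "B", "C", "D"),
#'                    first_occurrence = c(0, 0, 49, 0),
#'                    last_occurrence = 0)
#' cons <- data.frame(mrca_of = c("A;B;C;D", "C;D"),
#'                    age = c(99, 86), kind = "fixed")
#' node_ages(calibrate_tree(phy, tips, cons))
#' @export
calibrate_tree <- function(phy, tip_ages, constraints) {
  ntip <- ape::Ntip(phy)
  nnode <- phy$Nnode
  if (is.character(constraints$mrca_of))
    constraints$mrca_of <- lapply(strsplit(constraints$mrca_of, ";"),
                                  trimws)
  miss <- setdiff(phy$tip.label, tip_ages$taxon)
  if (length(miss))
    stop("no occurrence ages for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  age <- rep(NA_real_, ntip + nnode)
  age[seq_len(ntip)] <-
    tip_ages$first_occurrence[match(phy$tip.label, tip_ages$taxon)]

  ## resolve constraint target nodes
  cnode <- integer(nrow(constraints))
  for (i in seq_len(nrow(constraints))) {
    tips <- constraints$mrca_of[[i]]
    unknown <- setdiff(tips, phy$tip.label)
    if (length(unknown))
      stop("constraint ", i, ": unknown tip(s) ",
           paste(unknown, collapse = ", "), call. = FALSE)
    cnode[i] <- if (length(tips) == 1L) match(tips, phy$tip.label)
                else ape::getMRCA(phy, tips)
    if (is.na(cnode[i]) || cnode[i] <= ntip)
      stop("constraint ", i, ": MRCA of ", paste(tips, collapse = ", "),
           " is not an internal node", call. = FALSE)
  }
  if (anyDuplicated(cnode))
    stop("two constraints resolve to the same node", call. = FALSE)

  ## oldest dated descendant (tip first occurrences, then resolved
  ## constraint ages) for every internal node, computed tips-to-root
  po <- ape::reorder.phylo(phy, "postorder")$edge
  maxdesc <- rep(-Inf, ntip + nnode)
  maxdesc[seq_len(ntip)] <- age[seq_len(ntip)]
  resolved <- rep(NA_real_, ntip + nnode)
  for (e in seq_len(nrow(po))) {
    par <- po[e, 1]; ch <- po[e, 2]
    contrib <- maxdesc[ch]
    ci <- match(ch, cnode)
    if (!is.na(ci)) {
      a <- constraints$age[ci]
      if (constraints$kind[ci] == "fixed") {
        if (a < maxdesc[ch])
          stop(sprintf(
            "constraint conflict: node %d fixed at %.4g Ma is younger than a descendant dated at %.4g Ma",
            ch, a, maxdesc[ch]), call. = FALSE)
        resolved[ch] <- a
      } else {
        resolved[ch] <- max(a, maxdesc[ch])
      }
      contrib <- max(contrib, resolved[ch])
    }
    maxdesc[par] <- max(maxdesc[par], contrib)
  }
  root <- ntip + 1L
  ri <- match(root, cnode)
  if (is.na(ri))
    stop("the root must carry a fixed or minimum age constraint",
         call. = FALSE)
  a <- constraints$age[ri]
  resolved[root] <- if (constraints$kind[ri] == "fixed") {
    if (a < maxdesc[root])
      stop(sprintf(
        "constraint conflict: root fixed at %.4g Ma is younger than a descendant dated at %.4g Ma",
        a, maxdesc[root]), call. = FALSE)
    a
  } else max(a, maxdesc[root])

  ## preorder assignment: constrained nodes take their resolved age,
  ## unconstrained nodes the mean of parent age and oldest dated descendant
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  age[root] <- resolved[root]
  for (e in seq_len(nrow(pre))) {
    ch <- pre[e, 2]
    if (ch <= ntip) next
    age[ch] <- if (!is.na(resolved[ch])) resolved[ch]
               else (age[pre[e, 1]] + maxdesc[ch]) / 2
  }
  .as_dated(phy, age)
}

#' Brownian-motion covariance matrix of a dated tree
#'
#' Under Brownian motion the covariance of two tips is proportional to
#' their shared path length from the root: \code{C[i, j]} is the root age
#' minus the age of the most recent common ancestor of tips i and j
#' (elapsed time from the root to their divergence); the diagonal is each
#' tip's own elapsed time, so fossil tips have shallower diagonals than
#' extant ones.  Polytomies need no special handling.
#'
#' @param phy a \code{dated_phylo}.
#' @return symmetric positive-semidefinite tips-by-tips matrix with tip
#'   labels as dimnames.
#' @export
bm_covariance <- function(phy) {
  age <- node_ages(phy)
  ntip <- ape::Ntip(phy)
  root_age <- age[ntip + 1L]
  m <- ape::mrca(phy)
  C <- root_age - matrix(age[m], ntip, ntip)
  diag(C) <- root_age - age[seq_len(ntip)]
  dimnames(C) <- list(phy$tip.label, phy$tip.label)
  C
}

## Cholesky with escalating diagonal regularisation; near-singular C
## arises from zero-length interior branches (identical rows).  The
## jitter is used for inversion only, never for reported ages.
.chol_safe <- function(C) {
  eps <- 0
  for (try in 0:6) {
    R <- tryCatch(chol(C + diag(eps, nrow(C))), error = function(e) NULL)
    if (!is.null(R)) {
      if (eps > 0)
        message("covariance matrix regularised with diagonal jitter ",
                format(eps))
      return(R)
    }
    eps <- if (eps == 0) 1e-10 * mean(diag(C)) else eps * 100
  }
  stop("phylogenetic covariance matrix is singular; ",
       "consider jittering zero-length branches", call. = FALSE)
}

## GLS ingredients shared by K and lambda: ahat, residuals, quadratic forms
.gls_parts <- function(C, x) {
  R <- .chol_safe(C)
  Cinv <- chol2inv(R)
  one <- rep(1, length(x))
  ahat <- sum(Cinv %*% x) / sum(Cinv)
  e <- x - ahat
  list(Cinv = Cinv, ahat = ahat, e = e,
       logdet = 2 * sum(log(diag(R))),
       q = drop(t(e) %*% Cinv %*% e))
}

#' Blomberg's K phylogenetic signal with permutation test
#'
#' K compares the ratio of the trait's variance around the phylogenetic
#' (GLS) mean to its phylogenetically corrected variance with the value of
#' that ratio expected under Brownian motion on the given tree.  K = 1
#' matches the Brownian expectation, K < 1 indicates less resemblance
#' among relatives than Brownian motion predicts.  Significance is
#' assessed by permuting trait values across tips and counting
#' permutations with K at least as large as observed.
#'
#' @param phy a \code{dated_phylo}.
#' @param trait named numeric vector covering every tip.
#' @param n_permutations number of tip-label permutations for the p-value
#'   (default 999; 0 skips the test).
#' @param seed optional integer seed for the permutations.
#' @return an object of class \code{signal_result} with
#'   \code{statistic_name = "K"}, \code{estimate}, \code{p_value},
#'   \code{n_tips}, \code{n_permutations}.
#' @references Blomberg, Garland & Ives (2003) Evolution 57:717-745.
#' @export
blomberg_k <- function(phy, trait, n_permutations = 999, seed = NULL) {
  C <- bm_covariance(phy)
  x <- .match_trait(phy, trait)
  n <- length(x)
  if (n < 4) stop("Blomberg's K needs at least 4 tips", call. = FALSE)
  kstat <- function(x) {
    g <- .gls_parts(C, x)
    mse0 <- sum(g$e^2) / (n - 1)
    mse <- g$q / (n - 1)
    Cinv_sum <- sum(g$Cinv)
    expected <- (sum(diag(C)) - n / Cinv_sum) / (n - 1)
    (mse0 / mse) / expected
  }
  k_obs <- kstat(x)
  p <- NA_real_
  if (n_permutations > 0) {
    if (!is.null(seed)) set.seed(seed)
    k_perm <- replicate(n_permutations, kstat(sample(x)))
    p <- (1 + sum(k_perm >= k_obs)) / (n_permutations + 1)
  }
  structure(list(statistic_name = "K", estimate = k_obs,
                 log_likelihood = NA_real_, p_value = p, n_tips = n,
                 n_permutations = n_permutations, seed = seed),
            class = "signal_result")
}

## multiply off-diagonal covariances by lambda, diagonal unchanged
.lambda_transform <- function(C, lambda) {
  Cl <- C * lambda
  diag(Cl) <- diag(C)
  Cl
}

## profile log-likelihood of lambda: mean and rate profiled analytically
.lambda_loglik <- function(lambda, C, x) {
  n <- length(x)
  g <- .gls_parts(.lambda_transform(C, lambda), x)
  sigma2 <- g$q / n
  -0.5 * (n * log(2 * pi * sigma2) + g$logdet + n)
}

#' Pagel's lambda phylogenetic signal by maximum likelihood
#'
#' The lambda transform multiplies the off-diagonal entries of the
#' Brownian covariance by lambda, leaving the diagonal unchanged:
#' lambda = 0 erases phylogenetic covariance, lambda = 1 is plain Brownian
#' motion.  The estimate maximises the multivariate-normal log-likelihood
#' with the ancestral mean and the rate profiled out analytically; the
#' search runs on \[0, lambda_max\] where lambda_max (at most 1.2) keeps
#' the transformed covariance positive-definite.  The p-value is a
#' likelihood-ratio test against lambda = 0 on one degree of freedom.
#'
#' @inheritParams blomberg_k
#' @return a \code{signal_result} with \code{statistic_name = "lambda"},
#'   \code{estimate}, \code{log_likelihood}, \code{p_value},
#'   \code{n_tips}.
#' @references Pagel (1999) Nature 401:877-884.
#' @export
pagel_lambda <- function(phy, trait) {
  C <- bm_covariance(phy)
  x <- .match_trait(phy, trait)
  n <- length(x)
  if (n < 4) stop("Pagel's lambda needs at least 4 tips", call. = FALSE)
  ## C(1) = C is always a valid covariance, so the bound never drops
  ## below 1; above 1 it is tightened until C(lambda_max) stays PD
  lambda_max <- 1.2
  repeat {
    ok <- !inherits(tryCatch(chol(.lambda_transform(C, lambda_max)),
                             error = identity), "error")
    if (ok || lambda_max <= 1) break
    lambda_max <- max(1, lambda_max * 0.95)
    message("lambda search bound tightened to ", format(lambda_max))
  }
  opt <- stats::optimize(.lambda_loglik, c(0, lambda_max), C = C, x = x,
                         maximum = TRUE, tol = 1e-8)
  ## guard against optimize missing a boundary optimum
  cand <- unique(c(opt$maximum, 0, 1, lambda_max))
  cand <- cand[cand <= lambda_max]
  ll <- vapply(cand, .lambda_loglik, 0, C = C, x = x)
  best <- which.max(ll)
  ll0 <- .lambda_loglik(0, C, x)
  p <- stats::pchisq(2 * (ll[best] - ll0), df = 1, lower.tail = FALSE)
  structure(list(statistic_name = "lambda", estimate = cand[best],
                 log_likelihood = ll[best], p_value = p, n_tips = n,
                 n_permutations = NA_integer_, seed = NULL),
            class = "signal_result")
}

#' @export
print.signal_result <- function(x, ...) {
  cat(sprintf("%s = %.4f (n = %d tips)", x$statistic_name, x$estimate,
              x$n_tips))
  if (!is.na(x$p_value)) cat(sprintf(", p = %.4g", x$p_value))
  if (!is.na(x$log_likelihood))
    cat(sprintf(", logLik = %.4f", x$log_likelihood))
  cat("\n")
  invisible(x)
}

.match_trait <- function(phy, trait) {
  miss <- setdiff(phy$tip.label, names(trait))
  if (length(miss))
    stop("trait missing for tip(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  as.numeric(trait[phy$tip.label])
}

#' Squared-change parsimony ancestral state reconstruction
#'
#' Reconstructs a continuous trait at every internal node by minimising
#' the sum of squared changes along edges, with all branch lengths set to
#' one (no use of estimated divergence times).  Solved exactly by the
#' standard two-pass dynamic programme: a tips-to-root pass propagates,
#' per node, the quadratic cost of its subtree as a weight and a
#' conditional optimum; a root-to-tips pass then fixes each node at the
#' weighted compromise between its subtree and its parent's value.
#' Polytomies are handled natively.  The result is deterministic.
#'
#' @param phy a rooted \code{phylo}; branch lengths are ignored.
#' @param trait named numeric vector covering every tip.
#' @return an object of class \code{asr_result}: \code{ace}, the
#'   reconstructed value for every internal node (named by node number),
#'   and \code{cost}, the minimised sum of squared changes.
#' @references Maddison (1991) Systematic Zoology 40:304-314.
#' @export
parsimony_asr <- function(phy, trait) {
  x <- .match_trait(phy, trait)
  ntip <- ape::Ntip(phy)
  nn <- ntip + phy$Nnode
  po <- ape::reorder.phylo(phy, "postorder")$edge

  ## upward pass: subtree cost of node v at value z is A[v]*(z - m[v])^2 + const
  A <- numeric(nn)         # accumulated child weights
  m <- numeric(nn)         # conditional optimum
  m[seq_len(ntip)] <- x
  wsum <- numeric(nn); wmsum <- numeric(nn)
  for (e in seq_len(nrow(po))) {
    par <- po[e, 1]; ch <- po[e, 2]
    w <- if (ch <= ntip) 1 else A[ch] / (A[ch] + 1)
    wsum[par] <- wsum[par] + w
    wmsum[par] <- wmsum[par] + w * m[ch]
    A[par] <- wsum[par]
    m[par] <- wmsum[par] / wsum[par]
  }

  ## downward pass: root at its conditional optimum, then each internal
  ## node at the compromise between its subtree and its parent's value
  val <- numeric(nn)
  val[seq_len(ntip)] <- x
  root <- ntip + 1L
  val[root] <- m[root]
  pre <- po[rev(seq_len(nrow(po))), , drop = FALSE]
  for (e in seq_len(nrow(pre))) {
    ch <- pre[e, 2]
    if (ch <= ntip) next
    val[ch] <- (A[ch] * m[ch] + val[pre[e, 1]]) / (A[ch] + 1)
  }
  cost <- sum((val[phy$edge[, 1]] - val[phy$edge[, 2]])^2)
  ace <- val[(ntip + 1L):nn]
  names(ace) <- as.character((ntip + 1L):nn)
  structure(list(ace = ace, cost = cost), class = "asr_result")
}

#' @export
print.asr_result <- function(x, ...) {
  cat(sprintf("squared-change parsimony reconstruction: %d nodes, cost %.6g\n",
              length(x$ace), x$cost))
  invisible(x)
}
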