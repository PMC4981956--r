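#' Ordinary least-squares regression with a 95\% confidence band
#'
#' Linear regression of, e.g., body length on total vertebral count.  The
#' confidence band for the conditional mean uses the t distribution on
#' n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length, n >= 3; x must not be
#'   constant.
#' @return an object of class \code{anguimorph_regression}: slope,
#'   intercept, their standard errors, \code{r_squared}, \code{n}, and
#'   \code{ci95_band}, a function of new x returning a matrix with columns
#'   \code{fit}, \code{lower}, \code{upper}.
#' @export
fit_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  keep <- stats::complete.cases(x, y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations, got ", n, call. = FALSE)
  if (stats::sd(x) == 0) stop("x is constant: slope undefined", call. = FALSE)
  fit <- stats::lm(y ~ x)
  s <- summary(fit)
  band <- function(newx) {
    p <- stats::predict(fit, newdata = data.frame(x = newx),
                        interval = "confidence", level = 0.95)
    colnames(p) <- c("fit", "lower", "upper")
    p
  }
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = s$r.squared,
                 se_slope = s$coefficients[2, 2],
                 se_intercept = s$coefficients[1, 2],
                 n = n, ci95_band = band, lm = fit),
            class = "anguimorph_regression")
}

#' @export
print.anguimorph_regression <- function(x, ...) {
  cat(sprintf("OLS fit (n = %d): y = %.4g + %.4g x,  r^2 = %.4f\n",
              x$n, x$intercept, x$slope, x$r_squared))
  invisible(x)
}

## the eight body-shape variables entering the morphospace by default:
## exactly the inputs of the shape index
.default_pca_vars <- c("L_axis1", "L_axis2", "L_head_in_vertebrae",
                       "AR_head", "N_PCV", "AR_PCV", "N_CV", "AR_CV")

#' Principal component analysis of a taxa-by-variables table
#'
#' Morphospace construction over the body-shape variables.  The default
#' correlation mode standardises each variable (the variables mix mm,
#' counts and dimensionless ratios); covariance mode is available for
#' commensurate data.  Rows with missing values are excluded with a
#' warning naming the taxa.  Each loading column is oriented so that its
#' largest-magnitude entry is positive, a reproducible sign convention.
#'
#' @param table data frame or matrix of taxa (rows) by variables
#'   (columns); taxon ids taken from a \code{taxon_id} column or row
#'   names.
#' @param mode \code{"correlation"} (default) or \code{"covariance"}.
#' @param variables which columns to use; defaults to the eight
#'   shape-index inputs when present, otherwise all numeric columns.
#' @return an object of class \code{anguimorph_pca}: \code{variables},
#'   \code{loadings} (variables x components, orthonormal columns),
#'   \code{eigenvalues} (non-increasing), \code{scores} (taxa x
#'   components) and \code{variance_fraction}.
#' @export
run_pca <- function(table, mode = c("correlation", "covariance"),
                    variables = NULL) {
  mode <- match.arg(mode)
  table <- as.data.frame(table)
  ids <- if ("taxon_id" %in% names(table)) table$taxon_id
         else rownames(table)
  if (is.null(variables))
    variables <- if (all(.default_pca_vars %in% names(table)))
      .default_pca_vars
    else names(table)[vapply(table, is.numeric, TRUE)]
  if (length(variables) < 2)
    stop("PCA needs at least 2 variables", call. = FALSE)
  x <- as.matrix(table[, variables, drop = FALSE])
  storage.mode(x) <- "double"
  complete <- stats::complete.cases(x)
  if (any(!complete))
    warning("excluding incomplete row(s): ",
            paste(ids[!complete], collapse = ", "), call. = FALSE)
  x <- x[complete, , drop = FALSE]
  ids <- ids[complete]
  if (nrow(x) < 3)
    stop("PCA needs at least 3 complete rows, got ", nrow(x),
         call. = FALSE)
  pc <- stats::prcomp(x, center = TRUE, scale. = (mode == "correlation"))
  load <- pc$rotation
  scores <- pc$x
  ## orient each component so its largest-magnitude loading is positive
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  rownames(scores) <- ids
  ev <- pc$sdev^2
  structure(list(variables = variables, loadings = load,
                 eigenvalues = ev, scores = scores,
                 variance_fraction = ev / sum(ev), mode = mode),
            class = "anguimorph_pca")
}

#' @export
print.anguimorph_pca <- function(x, ...) {
  cat(sprintf("PCA (%s mode) of %d taxa x %d variables\n", x$mode,
              nrow(x$scores), length(x$variables)))
  cat("variance fractions:",
      paste(sprintf("%.3f", x$variance_fraction), collapse = " "), "\n")
  invisible(x)
}

## is point p inside (boundary-inclusive) the convex hull of pts?
## half-plane test against each hull edge, counter-clockwise ordering
.in_hull <- function(p, pts, tol = 1e-9) {
  h <- grDevices::chull(pts)            # chull returns clockwise order
  hp <- pts[rev(h), , drop = FALSE]     # make counter-clockwise
  m <- nrow(hp)
  scale <- max(abs(pts), 1)
  for (i in seq_len(m)) {
    a <- hp[i, ]; b <- hp[if (i == m) 1 else i + 1, ]
    cross <- (b[1] - a[1]) * (p[2] - a[2]) - (b[2] - a[2]) * (p[1] - a[1])
    if (cross < -tol * scale^2) return(FALSE)
  }
  TRUE
}

#' Morphospace overlap between two groups
#'
#' Builds the convex hull of each group's scores in a chosen component
#' plane and reports the taxa lying inside (boundary-inclusive) the other
#' group's hull — e.g. the fossil and living taxa falling in the shared
#' region of the extinct and extant eel morphospaces.
#'
#' @param pca an \code{anguimorph_pca}.
#' @param groups named character vector (or factor) mapping every scored
#'   taxon to one of exactly two group labels.
#' @param plane integer pair of component indices, default \code{c(1, 2)}.
#' @return an object of class \code{overlap_report}: \code{group_a},
#'   \code{group_b}, \code{overlap_taxa} (possibly empty character
#'   vector).
#' @export
morphospace_overlap <- function(pca, groups, plane = c(1, 2)) {
  sc <- pca$scores[, plane, drop = FALSE]
  taxa <- rownames(sc)
  missing <- setdiff(taxa, names(groups))
  if (length(missing))
    stop("no group label for taxa: ", paste(missing, collapse = ", "),
         call. = FALSE)
  g <- as.character(groups[taxa])
  labels <- sort(unique(g))
  if (length(labels) != 2)
    stop("morphospace_overlap needs exactly two groups, got ",
         length(labels), call. = FALSE)
  for (lab in labels)
    if (sum(g == lab) < 3)
      stop("group '", lab, "' has fewer than 3 taxa: hull degenerate",
           call. = FALSE)
  a <- sc[g == labels[1], , drop = FALSE]
  b <- sc[g == labels[2], , drop = FALSE]
  in_b <- rownames(a)[apply(a, 1, .in_hull, pts = b)]
  in_a <- rownames(b)[apply(b, 1, .in_hull, pts = a)]
  structure(list(group_a = labels[1], group_b = labels[2],
                 overlap_taxa = sort(c(in_b, in_a))),
            class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("morphospace overlap %s / %s: ", x$group_a, x$group_b))
  if (length(x$overlap_taxa))
    cat(paste(x$overlap_taxa, collapse = ", "), "\n")
  else cat("(disjoint hulls)\n")
  invisible(x)
}
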