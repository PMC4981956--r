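#' Select three representative vertebrae from a region
#'
#' The aspect-ratio terms of the shape index use "three selected" centra
#' per region.  The default, reproducible rule takes the centra whose
#' ordinals lie nearest 25\%, 50\% and 75\% of the region's span; explicit
#' ordinals may be supplied instead.
#'
#' @param vertebrae a \code{vertebra_table} for one taxon.
#' @param region \code{"precaudal"} or \code{"caudal"}.
#' @param indices optional explicit vertebra ordinals (length 3).
#' @return a three-row subset of \code{vertebrae}.
#' @export
select_vertebrae <- function(vertebrae, region = c("precaudal", "caudal"),
                             indices = NULL) {
  region <- match.arg(region)
  sub <- vertebrae[vertebrae$region == region, , drop = FALSE]
  if (!is.null(indices)) {
    if (length(indices) != 3L)
      stop("indices must name exactly three vertebrae", call. = FALSE)
    sub <- sub[match(indices, sub$index), , drop = FALSE]
    if (anyNA(sub$index))
      stop("requested vertebra ordinal absent from region ", region,
           call. = FALSE)
    return(sub)
  }
  if (nrow(sub) < 3L)
    stop("fewer than three measured ", region, " vertebrae", call. = FALSE)
  sub <- sub[order(sub$index), , drop = FALSE]
  picks <- unique(round(stats::quantile(seq_len(nrow(sub)),
                                        c(0.25, 0.5, 0.75), type = 1)))
  ## quantile ties only arise for tiny regions; pad with neighbours
  i <- 1L
  while (length(picks) < 3L) {
    cand <- setdiff(seq_len(nrow(sub)), picks)
    picks <- sort(c(picks, cand[i])); i <- i + 1L
  }
  sub[picks[1:3], , drop = FALSE]
}

#' Mean centrum aspect ratio over three vertebrae
#'
#' Arithmetic mean of centrum length / centrum height over exactly three
#' vertebrae of the requested region.  Length and height are measured in
#' the plane of the secondary body axis (body depth).
#'
#' @param measurements a three-row \code{vertebra_table} subset.
#' @param region region the measurements must come from.
#' @return the dimensionless mean aspect ratio.
#' @export
mean_aspect_ratio <- function(measurements,
                              region = c("precaudal", "caudal")) {
  region <- match.arg(region)
  if (nrow(measurements) != 3L)
    stop("mean_aspect_ratio needs exactly three vertebrae, got ",
         nrow(measurements), call. = FALSE)
  if (any(measurements$region != region))
    stop("measurement from wrong region (expected ", region, ")",
         call. = FALSE)
  if (any(measurements$centrum_height == 0))
    stop("zero centrum height for vertebra ",
         paste(measurements$index[measurements$centrum_height == 0],
               collapse = ", "), call. = FALSE)
  mean(measurements$centrum_length / measurements$centrum_height)
}

#' Vertebrate shape index (VSI)
#'
#' Computes, per specimen, the four summands and their total:
#' \deqn{VSI = L_{axis1}/L_{axis2} + L_{head.in.vertebrae} \times AR_{head}
#'       + N_{PCV} \times AR_{PCV} + N_{CV} \times AR_{CV}}
#' where \eqn{L_{axis1}} is standard length, \eqn{L_{axis2}} the secondary
#' body axis (maximum depth, or width), the head term counts vertebral
#' centra spanning the head weighted by the head aspect ratio, and the
#' precaudal/caudal terms multiply vertebral counts by mean centrum aspect
#' ratios.  All terms are ratios or counts times ratios, so the index is
#' invariant under uniform rescaling of the linear measurements.
#'
#' @param specimens a \code{specimen_table} (one or more rows).
#' @return data frame with \code{taxon_id}, the four terms
#'   (\code{term_ratio}, \code{term_head}, \code{term_pcv},
#'   \code{term_cv}) and their sum \code{vsi}.
#' @examples
#' rec <- data.frame(taxon_id = "demo", status = "extant", clade = NA,
#'                   L_axis1 = 100, L_axis2 = 10, head_length = 12,
#'                   L_head_in_vertebrae = 5, N_PCV = 50, N_CV = 60,
#'                   AR_head = 2, AR_PCV = 3, AR_CV = 2.5)
#' compute_vsi(rec)   # vsi = 10 + 10 + 150 + 150 = 320
#' @export
compute_vsi <- function(specimens) {
  specimens <- validate_specimens(as.data.frame(specimens))
  needed <- c("L_axis1", "L_axis2", "L_head_in_vertebrae", "AR_head",
              "N_PCV", "AR_PCV", "N_CV", "AR_CV")
  for (i in seq_len(nrow(specimens))) {
    absent <- needed[vapply(needed,
                            function(f) is.na(specimens[[f]][i]), TRUE)]
    if (length(absent))
      stop("compute_vsi: taxon ", specimens$taxon_id[i],
           " is missing field(s): ", paste(absent, collapse = ", "),
           call. = FALSE)
  }
  if (any(specimens$L_axis2 == 0))
    stop("compute_vsi: L_axis2 is zero", call. = FALSE)
  out <- data.frame(
    taxon_id   = specimens$taxon_id,
    term_ratio = specimens$L_axis1 / specimens$L_axis2,
    term_head  = specimens$L_head_in_vertebrae * specimens$AR_head,
    term_pcv   = specimens$N_PCV * specimens$AR_PCV,
    term_cv    = specimens$N_CV * specimens$AR_CV)
  out$vsi <- out$term_ratio + out$term_head + out$term_pcv + out$term_cv
  class(out) <- unique(c("vsi_table", class(out)))
  out
}

#' Derive specimen aspect-ratio fields from per-vertebra measurements
#'
#' Fills \code{AR_PCV} and \code{AR_CV} of a specimen table from a
#' vertebra table using [select_vertebrae()] and [mean_aspect_ratio()].
#'
#' @param specimens a \code{specimen_table}.
#' @param vertebrae a \code{vertebra_table} covering the same taxa.
#' @return the specimen table with aspect-ratio columns filled.
#' @export
fill_aspect_ratios <- function(specimens, vertebrae) {
  for (i in seq_len(nrow(specimens))) {
    v <- vertebrae[vertebrae$taxon_id == specimens$taxon_id[i], ,
                   drop = FALSE]
    if (!nrow(v)) next
    specimens$AR_PCV[i] <-
      mean_aspect_ratio(select_vertebrae(v, "precaudal"), "precaudal")
    specimens$AR_CV[i] <-
      mean_aspect_ratio(select_vertebrae(v, "caudal"), "caudal")
  }
  specimens
}
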