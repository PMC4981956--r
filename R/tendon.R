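#' Lateral-tendon length from ossified myoseptal bones
#'
#' In fossil eels the lateral tendon of each myoseptum is not preserved
#' directly, but the ossified epineural (ENB) and epipleural (EPB) bones
#' are, and the number of vertebrae they traverse estimates the tendon's
#' length.  An element attaching on centrum N and crossing k subsequent
#' centra ("N + k" notation) gives an attachment span of k + 1 vertebrae;
#' the tendon itself extends one further segment (the anterior cones of
#' the myoseptum span one more vertebra, as observed in extant
#' \emph{Anguilla}), so the tendon length is k + 2 vertebrae.
#'
#' Where the traversal count is a range ("N + 1/2": at least one, not more
#' than two), the point estimate uses the upper bound \code{k_max}; both
#' bounds are reported.  Fractional counts (e.g. 2.5) are carried exactly.
#'
#' @param obs a \code{tendon_table} of ENB/EPB observations (one or more
#'   rows).  Myorhabdoid tendons (MT) and posterior oblique tendons (POT)
#'   do not trace the lateral tendon and are rejected.
#' @return data frame with per-observation \code{attachment_span_vertebrae}
#'   (= k_max + 1), \code{tendon_length_vertebrae} (= k_max + 2),
#'   \code{tendon_length_vertebrae_min} (= k_min + 2) and an
#'   \code{inferred} flag (FALSE here; see [mirror_missing_side()]).
#' @examples
#' obs <- data.frame(taxon_id = "Paranguilla_tigrina", element = "ENB",
#'                   side = "epaxial", k_min = 2.5, k_max = 2.5,
#'                   tl_start = 60, tl_end = 97)
#' lateral_tendon_length(obs)$tendon_length_vertebrae  # 4.5
#' @export
lateral_tendon_length <- function(obs) {
  obs <- validate_tendons(as.data.frame(obs))
  bad <- !obs$element %in% c("ENB", "EPB")
  if (any(bad))
    stop("lateral_tendon_length: element(s) ",
         paste(unique(obs$element[bad]), collapse = ", "),
         " do not define the lateral tendon (need ENB or EPB)",
         call. = FALSE)
  if (any(obs$k_max < 0))
    stop("negative traversal count", call. = FALSE)
  out <- data.frame(
    taxon_id = obs$taxon_id,
    element  = obs$element,
    side     = obs$side,
    k_min    = obs$k_min,
    k_max    = obs$k_max,
    attachment_span_vertebrae   = obs$k_max + 1,
    tendon_length_vertebrae     = obs$k_max + 2,
    tendon_length_vertebrae_min = obs$k_min + 2,
    tl_start = obs$tl_start,
    tl_end   = obs$tl_end,
    inferred = FALSE)
  class(out) <- unique(c("tendon_estimate", class(out)))
  out
}

#' Mirror a tendon estimate onto an unpreserved side
#'
#' Myosepta are epaxially and hypaxially symmetrical, so when only one
#' side of a fossil preserves ossified tendons the other side's estimate
#' is taken to equal it, flagged \code{inferred}.
#'
#' @param est a \code{tendon_estimate} data frame.
#' @return the estimate table with mirrored rows appended for taxa that
#'   have observations on one side only.
#' @export
mirror_missing_side <- function(est) {
  extra <- list()
  for (tax in unique(est$taxon_id)) {
    sides <- unique(est$side[est$taxon_id == tax])
    if (length(sides) == 1L) {
      m <- est[est$taxon_id == tax, , drop = FALSE]
      m$side <- setdiff(.side_levels, sides)
      m$element <- ifelse(m$element == "ENB", "EPB", "ENB")
      m$inferred <- TRUE
      extra[[tax]] <- m
    }
  }
  out <- rbind(est, do.call(rbind, extra))
  rownames(out) <- NULL
  out
}

#' Tendon length as a fraction of total body length
#'
#' Converts a tendon length expressed in vertebral units into a fraction
#' of total length by summing the centrum lengths it spans, starting at a
#' given vertebra; a fractional final vertebra is pro-rated linearly.
#'
#' @param tendon_length_vertebrae tendon length in vertebrae (may be
#'   fractional).
#' @param vertebra_lengths ordered centrum lengths in mm for the whole
#'   column.
#' @param total_length total body length in mm.
#' @param at_vertebra 1-based ordinal of the vertebra where the span
#'   starts.
#' @return the spanned length divided by \code{total_length}.
#' @export
tendon_length_fraction <- function(tendon_length_vertebrae,
                                   vertebra_lengths, total_length,
                                   at_vertebra = 1L) {
  stopifnot(total_length > 0, tendon_length_vertebrae > 0,
            at_vertebra >= 1)
  n_full <- floor(tendon_length_vertebrae)
  frac <- tendon_length_vertebrae - n_full
  last <- at_vertebra + ceiling(tendon_length_vertebrae) - 1
  if (last > length(vertebra_lengths))
    stop(sprintf(
      "span of %.3g vertebrae from ordinal %d exceeds the %d measured centra",
      tendon_length_vertebrae, at_vertebra, length(vertebra_lengths)),
      call. = FALSE)
  idx_full <- seq(at_vertebra, length.out = n_full)
  spanned <- sum(vertebra_lengths[idx_full])
  if (frac > 0)
    spanned <- spanned + frac * vertebra_lengths[last]
  spanned / total_length
}

#' Position along the body in percent of total length
#'
#' @param position_mm distance from the snout in mm.
#' @param total_length total body length in mm.
#' @return position as a percentage of total length in \[0, 100\].
#' @export
percent_tl <- function(position_mm, total_length) {
  stopifnot(total_length > 0)
  if (any(position_mm < 0 | position_mm > total_length))
    stop("position outside [0, total_length]", call. = FALSE)
  100 * position_mm / total_length
}

#' Map vertebra ordinals to axial positions
#'
#' The posterior margin of vertebra i lies at head length plus the
#' cumulative centrum lengths through i, measured from the snout.
#'
#' @param head_length head length in mm.
#' @param centrum_lengths ordered centrum lengths in mm.
#' @param ordinal 1-based vertebra ordinal(s).
#' @return position(s) in mm from the snout.
#' @export
vertebra_position <- function(head_length, centrum_lengths, ordinal) {
  stopifnot(head_length >= 0, all(centrum_lengths > 0),
            all(ordinal >= 1), all(ordinal <= length(centrum_lengths)))
  head_length + cumsum(centrum_lengths)[ordinal]
}
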