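#' Offensive effectiveness
#'
#' Percentage of attacks that scored: \code{100 * (ippon + wazari) / attacks}.
#' Shido is a penalty, not a score, and does not enter the numerator. With
#' zero attacks the ratio is undefined (0/0 is not "zero effectiveness") and
#' \code{NA} is returned; downstream correlations drop missing values
#' pairwise.
#'
#' @param ippon,wazari,attacks Nonnegative counts; \code{ippon + wazari}
#'   must not exceed \code{attacks}.
#' @return Effectiveness in percent, or \code{NA} when \code{attacks == 0}.
#' @examples
#' effectiveness(2, 1, 16)  # 18.75
#' @export
effectiveness <- function(ippon, wazari, attacks) {
  stopifnot(ippon >= 0, wazari >= 0, attacks >= 0, ippon + wazari <= attacks)
  if (attacks == 0) return(NA_real_)
  100 * (ippon + wazari) / attacks
}

#' Offensive efficiency
#'
#' Weighted score sum for one combat: \code{10 * ippon + 7 * wazari} (a.u.).
#'
#' @param ippon,wazari Nonnegative counts.
#' @return Efficiency in arbitrary units.
#' @examples
#' efficiency(2, 1)  # 27
#' @export
efficiency <- function(ippon, wazari) {
  stopifnot(ippon >= 0, wazari >= 0)
  10 * ippon + 7 * wazari
}

#' Post-minus-pre change
#'
#' The delta statistic used for lactate, heart rate and RPE:
#' \code{post - pre}. Order-sensitive by contract.
#'
#' @param post,pre Finite values at the post- and pre-combat moments.
#' @return \code{post - pre}.
#' @export
delta <- function(post, pre) {
  stopifnot(is.finite(post), is.finite(pre))
  post - pre
}

#' Recovery rate of decay
#'
#' Percent drop from the recovery maximum to the minimum:
#' \code{100 * (maximum - minimum) / maximum}. Scale-invariant in its two
#' arguments.
#'
#' @param maximum Peak value, must be positive.
#' @param minimum Minimum value at or after the peak; \code{minimum <= maximum}.
#' @return Rate of decay in percent.
#' @examples
#' rate_of_decay(10.1, 7.7)  # ~23.8
#' @export
rate_of_decay <- function(maximum, minimum) {
  if (!is.finite(maximum) || maximum <= 0) stop("maximum must be positive")
  stopifnot(minimum <= maximum)
  100 * (maximum - minimum) / maximum
}

#' Time-motion summary of a match record
#'
#' Decomposes a match into combat blocks (a standing phase optionally
#' followed by a groundwork phase) separated by pauses and computes the ten
#' time-motion parameters:
#' \describe{
#'   \item{CF}{combat frequency = number of combat blocks}
#'   \item{TSCT, TGCT, TPT}{total standing, groundwork and pause time (s)}
#'   \item{ACT}{average combat-block duration = (TSCT + TGCT) / CF}
#'   \item{APT}{average pause duration = TPT / (CF - 1); \code{NA} with no pause}
#'   \item{ASCT}{mean standing-phase duration}
#'   \item{AGCT}{mean groundwork-phase duration over blocks containing one;
#'     \code{NA} if no block does}
#'   \item{TAtt}{mean gap between consecutive attack onsets on the combat
#'     clock (pauses excluded); with fewer than two attacks it equals the
#'     accumulated combat time}
#'   \item{EP_ratio}{effort-pause ratio ACT / APT}
#' }
#'
#' @param match A \code{judo_match} object from \code{\link{simulate_match}},
#'   or any list with a \code{segments} data frame (\code{kind},
#'   \code{duration}) and an \code{attacks} data frame with an
#'   \code{onset_combat} column.
#' @return A list with the fields above.
#' @export
time_motion_summary <- function(match) {
  seg <- match$segments
  if (is.null(seg) || nrow(seg) == 0L) stop("match has no segments")
  stopifnot(all(seg$kind %in% c("standing", "groundwork", "pause")),
            all(seg$duration >= 0))
  ## a combat block starts at every standing segment
  block_id <- cumsum(seg$kind == "standing")
  if (any(block_id == 0)) stop("match must start with a standing segment")
  combat <- seg$kind != "pause"
  CF <- max(block_id[combat])
  TSCT <- sum(seg$duration[seg$kind == "standing"])
  TGCT <- sum(seg$duration[seg$kind == "groundwork"])
  TPT <- sum(seg$duration[seg$kind == "pause"])
  ACT <- (TSCT + TGCT) / CF
  APT <- if (CF > 1) TPT / (CF - 1) else NA_real_
  ASCT <- mean(seg$duration[seg$kind == "standing"])
  gw <- seg$duration[seg$kind == "groundwork"]
  AGCT <- if (length(gw)) mean(gw) else NA_real_
  onsets <- sort(match$attacks$onset_combat)
  TAtt <- if (length(onsets) >= 2) mean(diff(onsets)) else TSCT + TGCT
  EP <- if (is.na(APT) || APT <= 0) NA_real_ else ACT / APT
  list(CF = CF, ACT = ACT, APT = APT, ASCT = ASCT, AGCT = AGCT,
       TAtt = TAtt, TSCT = TSCT, TGCT = TGCT, TPT = TPT, EP_ratio = EP)
}

#' Summary statistics of a physiological recovery series
#'
#' From a series sampled at \code{rest}, \code{pre}, \code{post} and every
#' 2 min of recovery up to 10 min, computes pre, post, delta (post - pre),
#' the recovery peak (maximum over post and the recovery points; rest and
#' pre are excluded, the peak being a recovery phenomenon), the time to
#' reach it (minutes after combat; post = 0), and the rate of decay from the
#' peak to the minimum at or after the peak. Ties in the peak resolve to the
#' earliest sampling time.
#'
#' @param series A \code{physio_series} object or named numeric vector with
#'   elements \code{rest}, \code{pre}, \code{post}, \code{rec2}, \code{rec4},
#'   \code{rec6}, \code{rec8}, \code{rec10}.
#' @return A list with \code{pre}, \code{post}, \code{delta}, \code{peak},
#'   \code{time_to_peak}, \code{rate_of_decay}.
#' @export
physio_summary <- function(series) {
  v <- if (is.list(series) && !is.null(series$values)) series$values else series
  need <- c("rest", "pre", "post", "rec2", "rec4", "rec6", "rec8", "rec10")
  if (!all(need %in% names(v)) || anyNA(v[need])) {
    stop("incomplete physiological series: need ",
         paste(setdiff(need, names(v)), collapse = ", "))
  }
  v <- as.numeric(v[need])
  names(v) <- need
  times <- c(post = 0, rec2 = 2, rec4 = 4, rec6 = 6, rec8 = 8, rec10 = 10)
  path <- v[names(times)]
  i_peak <- which.max(path)  # which.max takes the first maximum: earliest time
  peak <- path[[i_peak]]
  after <- path[seq(i_peak, length(path))]
  list(pre = v[["pre"]], post = v[["post"]],
       delta = delta(v[["post"]], v[["pre"]]),
       peak = peak,
       time_to_peak = unname(times[i_peak]),
       rate_of_decay = rate_of_decay(peak, min(after)))
}
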