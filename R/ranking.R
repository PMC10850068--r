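## Quality-based ranking of simulations.

.sort_keys <- c("P_sn1", "P_sn2", "P_hg", "P_total", "FF_q")

#' Rank simulations by quality against experiments
#'
#' Orders simulations by one of the quality measures: order-parameter
#' fragment qualities (\code{P_sn1}, \code{P_sn2}, \code{P_hg},
#' \code{P_total}; best value 1, sorted descending) or the form-factor
#' quality \code{FF_q} (best value 0, sorted ascending). Simulations whose
#' conformational sampling is clearly unconverged (\code{tau_rel > 1.3}) are
#' discarded before ranking. Ties are broken by entry id so the order is
#' reproducible.
#'
#' @param reports data.frame with columns \code{entry_id}, \code{tau_rel} and
#'   the requested quality column (rows with \code{NA} quality are dropped).
#' @param sort_key one of \code{"P_sn1"}, \code{"P_sn2"}, \code{"P_hg"},
#'   \code{"P_total"}, \code{"FF_q"}.
#' @param tau_rel_max discard threshold for \code{tau_rel} (default 1.3).
#' @return data.frame of ranking records (\code{entry_id}, \code{sort_key},
#'   \code{value}, \code{tau_rel}), best first.
#' @export
rankSimulations <- function(reports, sort_key = "P_sn1", tau_rel_max = 1.3) {
  if (!sort_key %in% .sort_keys)
    stop("usage error: unknown sort key '", sort_key, "'; use one of: ",
         paste(.sort_keys, collapse = ", "))
  reports <- as.data.frame(reports)
  if (!sort_key %in% names(reports))
    stop("usage error: reports carry no column '", sort_key, "'")
  keep <- !(is.finite(reports$tau_rel) & reports$tau_rel > tau_rel_max)
  keep <- keep & !is.na(reports[[sort_key]])
  r <- reports[keep, , drop = FALSE]
  decreasing <- sort_key != "FF_q"
  v <- r[[sort_key]]
  ord <- order(if (decreasing) -v else v, r$entry_id)
  data.frame(entry_id = r$entry_id[ord], sort_key = sort_key,
             value = v[ord], tau_rel = r$tau_rel[ord],
             stringsAsFactors = FALSE)
}
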