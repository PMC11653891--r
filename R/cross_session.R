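#' Match neurons across two sessions by centroid proximity
#'
#' Greedy globally-nearest matching: among all unmatched cross-session pairs
#' whose centroid distance is at most `max_dist` pixels, the closest pair is
#' matched first, repeatedly, so no neuron is matched twice. Ties are broken
#' deterministically by (id_a, id_b) lexicographic order. The 7-pixel default
#' is the standard criterion for identifying the same cell across miniscope
#' sessions.
#'
#' @param map_a,map_b neuron maps (`neuron_id`, `x_px`, `y_px`) of the two
#'   sessions.
#' @param max_dist maximum centroid distance, pixels (default 7).
#' @return An object of class `identity_map`: data.frame with `id_a`, `id_b`,
#'   `dist_px`, plus attributes `unmatched_a`, `unmatched_b`.
#' @export
match_neurons <- function(map_a, map_b, max_dist = 7) {
  if (nrow(map_a) == 0 || nrow(map_b) == 0) stop("both maps must be nonempty")
  dx <- outer(map_a$x_px, map_b$x_px, "-")
  dy <- outer(map_a$y_px, map_b$y_px, "-")
  d <- sqrt(dx^2 + dy^2)
  cand <- which(d <= max_dist, arr.ind = TRUE)
  if (nrow(cand) > 0) {
    ord <- order(d[cand], map_a$neuron_id[cand[, 1]],
                 map_b$neuron_id[cand[, 2]])
    cand <- cand[ord, , drop = FALSE]
  }
  used_a <- logical(nrow(map_a)); used_b <- logical(nrow(map_b))
  ia <- integer(0); ib <- integer(0)
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1]; j <- cand[k, 2]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      ia <- c(ia, i); ib <- c(ib, j)
    }
  }
  out <- data.frame(
    id_a = map_a$neuron_id[ia], id_b = map_b$neuron_id[ib],
    dist_px = d[cbind(ia, ib)], stringsAsFactors = FALSE
  )
  structure(out,
            unmatched_a = map_a$neuron_id[!used_a],
            unmatched_b = map_b$neuron_id[!used_b],
            class = c("identity_map", "data.frame"))
}

#' Normalize per-neuron rates to a baseline session
#'
#' Divides each session's per-neuron rate by the same neuron's rate in the
#' designated baseline session (conventionally the last baseline day).
#' Neurons with zero or missing baseline rate are excluded; their count is
#' recorded in the `n_excluded` attribute.
#'
#' @param rates_by_session named list of named numeric vectors (session ->
#'   neuron id -> events/min); neuron names identify matched cells.
#' @param baseline_session name of the baseline session in the list.
#' @return named list of named numeric vectors of baseline-normalized rates
#'   (baseline session omitted), with attribute `n_excluded`.
#' @export
normalize_to_baseline <- function(rates_by_session, baseline_session) {
  if (!baseline_session %in% names(rates_by_session)) {
    stop("baseline session not found: ", baseline_session)
  }
  base <- rates_by_session[[baseline_session]]
  usable <- names(base)[!is.na(base) & base > 0]
  n_excluded <- length(base) - length(usable)
  others <- setdiff(names(rates_by_session), baseline_session)
  out <- lapply(rates_by_session[others], function(r) {
    shared <- intersect(names(r), usable)
    r[shared] / base[shared]
  })
  attr(out, "n_excluded") <- n_excluded
  out
}

#' Classify stress response from baseline-normalized rates
#'
#' Partitions neurons by their baseline-normalized activation rate:
#' `activated` above `upper` (default 1.75), `inhibited` below `lower`
#' (default 0.5), `non_responsive` in the closed interval between. The
#' defaults are the median-derived thresholds used for stress-response
#' classification in chronically imaged hippocampal ensembles.
#'
#' @param normalized named numeric vector of normalized rates.
#' @param upper activation threshold (strict).
#' @param lower inhibition threshold (strict).
#' @return named factor with levels `activated`, `inhibited`,
#'   `non_responsive`.
#' @export
classify_response <- function(normalized, upper = 1.75, lower = 0.5) {
  if (lower >= upper) stop("lower must be < upper")
  cls <- ifelse(normalized > upper, "activated",
                ifelse(normalized < lower, "inhibited", "non_responsive"))
  factor(cls, levels = c("activated", "inhibited", "non_responsive"))
}

#' Response-class fractions
#'
#' @param classification factor from [classify_response()].
#' @return named numeric vector of percentages (sums to 100).
#' @export
response_fractions <- function(classification) {
  if (length(classification) == 0) stop("no classified neurons")
  100 * table(classification) / length(classification)
}

#' Per-mouse normalization of a recording-level metric
#'
#' Divides each recording's metric value by the mean of that mouse's baseline
#' recordings, removing between-animal scale differences.
#'
#' @param values numeric vector, one value per recording.
#' @param mouse_ids character vector, the mouse of each recording.
#' @param baseline_means named numeric vector, mouse id -> mean baseline
#'   value (> 0).
#' @return numeric vector of normalized values.
#' @export
per_mouse_normalize <- function(values, mouse_ids, baseline_means) {
  if (length(values) != length(mouse_ids)) {
    stop("values and mouse_ids must have equal length")
  }
  miss <- setdiff(unique(mouse_ids), names(baseline_means))
  if (length(miss) > 0) stop("no baseline mean for: ", paste(miss, collapse = ", "))
  b <- baseline_means[mouse_ids]
  if (any(!is.finite(b)) || any(b <= 0)) stop("baseline means must be > 0")
  unname(values / b)
}
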