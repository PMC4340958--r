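#' Copies per cell from abundance relative to a reference transcript
#'
#' Converts an abundance expressed per 10^6 copies of a reference transcript
#' into absolute copies per cell, given the reference's absolute abundance:
#' `target_per_1e6_ref * 1e-6 * ref_copies_per_cell`. The published worked
#' example is Cd69 mRNA at 25,000 per 10^6 copies of B2M with ~215 B2M
#' copies per cell, giving 5.375 (~6) Cd69 mRNA copies per activated cell.
#'
#' @param target_per_1e6_ref Target abundance per 10^6 reference copies
#'   (>= 0, vectorised).
#' @param ref_copies_per_cell Reference copies per cell (>= 0).
#' @param round_to_integer Round the result to the nearest whole copy.
#' @return Copies of the target per cell.
#' @examples
#' copies_from_reference_ratio(25000, 215)        # 5.375
#' copies_from_reference_ratio(25000, 215, TRUE)  # 5
#' @export
copies_from_reference_ratio <- function(target_per_1e6_ref,
                                        ref_copies_per_cell,
                                        round_to_integer = FALSE) {
  if (any(target_per_1e6_ref < 0) || any(ref_copies_per_cell < 0)) {
    abort("abundances and copy numbers must be >= 0.")
  }
  out <- target_per_1e6_ref * 1e-6 * ref_copies_per_cell
  if (round_to_integer) round(out) else out
}

#' Copies per cell from small-RNA cloning frequencies
#'
#' Anchors the total cellular microRNA pool on one microRNA of known
#' absolute abundance: if the anchor was cloned at `anchor_freq_per_1e6`
#' reads per 10^6 microRNAs and is present at `anchor_copies` per cell
#' (a single value or a `c(low, high)` range), the pool is
#' `anchor_copies / (anchor_freq_per_1e6 * 1e-6)` and the target's copies
#' are `pool * target_freq_per_1e6 * 1e-6`. The published anchoring uses
#' miR-181a (89,884 per 10^6 reads; 400-800 copies per DP thymocyte) to
#' place miR-17 (1,465 per 10^6) at roughly 6.5-13 copies per cell.
#'
#' @param target_freq_per_1e6 Target cloning frequency per 10^6 microRNAs.
#' @param anchor_freq_per_1e6 Anchor cloning frequency per 10^6 (> 0).
#' @param anchor_copies Anchor copies per cell, value or `c(low, high)`.
#' @return A tibble with `low` and `high` copies per cell (equal when
#'   `anchor_copies` is a single value).
#' @examples
#' copies_from_cloning_frequency(1465, 89884, c(400, 800))
#' @export
copies_from_cloning_frequency <- function(target_freq_per_1e6,
                                          anchor_freq_per_1e6,
                                          anchor_copies) {
  if (anchor_freq_per_1e6 <= 0) {
    abort("`anchor_freq_per_1e6` must be positive.")
  }
  if (any(target_freq_per_1e6 < 0) || any(anchor_copies < 0)) {
    abort("frequencies and copy numbers must be >= 0.")
  }
  rng <- range(anchor_copies)
  pool <- rng / (anchor_freq_per_1e6 * 1e-6)
  tibble::tibble(low = pool[1] * target_freq_per_1e6 * 1e-6,
                 high = pool[2] * target_freq_per_1e6 * 1e-6)
}

#' Relative expression by the comparative CT method
#'
#' qPCR normalisation against the geometric average of two housekeeping
#' genes: `2^-(ct_target - (ct_ref_1 + ct_ref_2)/2)`. Averaging the
#' reference CT values arithmetically is exactly the geometric mean of the
#' reference expression levels, since expression is `2^-CT`.
#'
#' @param ct_target,ct_ref_1,ct_ref_2 Cycle-threshold values (finite;
#'   vectorised).
#' @return Relative expression (1 when the target CT equals the reference
#'   mean; halves per extra cycle).
#' @examples
#' delta_ct_normalize(25, 20, 22)  # 2^-4 = 0.0625
#' @export
delta_ct_normalize <- function(ct_target, ct_ref_1, ct_ref_2) {
  if (any(!is.finite(c(ct_target, ct_ref_1, ct_ref_2)))) {
    abort("CT values must be finite.")
  }
  2^(-(ct_target - (ct_ref_1 + ct_ref_2) / 2))
}

#' Copy-number estimates for a table of cloning frequencies
#'
#' Convenience wrapper applying [copies_from_cloning_frequency()] to each
#' row of a `(name, frequency)` table against one anchor.
#'
#' @param freqs A data frame with columns `name` and `freq_per_1e6`.
#' @param anchor_freq_per_1e6,anchor_copies Anchor as in
#'   [copies_from_cloning_frequency()].
#' @return A tibble with `name`, `freq_per_1e6`, `low`, `high`.
#' @export
copies_from_frequency_table <- function(freqs, anchor_freq_per_1e6,
                                        anchor_copies) {
  if (!all(c("name", "freq_per_1e6") %in% names(freqs))) {
    abort("`freqs` must have columns `name` and `freq_per_1e6`.")
  }
  dplyr::bind_cols(
    tibble::as_tibble(freqs[c("name", "freq_per_1e6")]),
    copies_from_cloning_frequency(freqs$freq_per_1e6, anchor_freq_per_1e6,
                                  anchor_copies)
  )
}
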