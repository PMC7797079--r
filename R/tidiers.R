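#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy an occupancy profile
#'
#' @param x an `occupancy_profile`.
#' @param ... unused.
#' @return a plain tibble, one row per sense codon.
#' @export
tidy.occupancy_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("codon", "amino_acid", "mean_occupancy",
                                 "n_genes", "stderr")])
}

#' @rdname tidy.occupancy_profile
#' @export
glance.occupancy_profile <- function(x, ...) {
  tibble::tibble(
    n_codons = nrow(x),
    n_codons_defined = sum(!is.na(x$mean_occupancy)),
    max_occupancy_codon = x$codon[which.max(x$mean_occupancy)],
    max_occupancy = max(x$mean_occupancy, na.rm = TRUE)
  )
}

#' Tidy a metagene profile
#'
#' @param x a `metagene_profile`.
#' @param ... unused.
#' @return a plain tibble `position`, `mean_density`, `n_occurrences`.
#' @export
tidy.metagene_profile <- function(x, ...) {
  tibble::as_tibble(unclass(x)[c("position", "mean_density",
                                 "n_occurrences")])
}

#' @rdname tidy.metagene_profile
#' @export
glance.metagene_profile <- function(x, ...) {
  tibble::tibble(
    target_codon = attr(x, "target_codon"),
    window = attr(x, "window"),
    occurrences_total = attr(x, "occurrences_total"),
    used = attr(x, "used"),
    boundary_dropped = attr(x, "boundary_dropped"),
    zero_read_dropped = attr(x, "zero_read_dropped")
  )
}

#' Tidy a bin-trend result
#'
#' @param x a `bin_trend`.
#' @param ... unused.
#' @return `tidy()`: the per-bin summary tibble; `glance()`: one row with
#'   the trend statistic and its permutation p-value.
#' @export
tidy.bin_trend <- function(x, ...) x$summary

#' @rdname tidy.bin_trend
#' @export
glance.bin_trend <- function(x, ...) {
  tibble::tibble(trend = x$trend, p_value = x$p_value, n_perm = x$n_perm)
}
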