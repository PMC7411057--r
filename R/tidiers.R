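#' Tidiers for darkfieldr result objects
#'
#' Broom-style methods: `tidy()` returns a tibble of the per-element results,
#' `glance()` a one-row summary.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @export
tidy.chord_distribution <- function(x, ...) {
  tibble(chord_um = x$chords)
}

#' @rdname tidiers
#' @export
glance.chord_distribution <- function(x, ...) {
  tibble(mcl_um = x$mcl_um, mcl_se_um = x$mcl_se_um, n_chords = x$n_chords,
         n_lines = x$n_lines, n_excluded = x$n_excluded, seed = x$seed)
}

#' @rdname tidiers
#' @export
tidy.material_record <- function(x, ...) {
  dplyr::mutate(x$bins, material = x$name, mcl_um = x$mcl$mcl_um,
                ratio_low_over_high = x$ratio_low_over_high,
                .before = 1)
}

#' @rdname tidiers
#' @export
tidy.xdf_correlation <- function(x, ...) x$scatter

#' @rdname tidiers
#' @export
glance.xdf_correlation <- function(x, ...) {
  tibble(n_materials = nrow(x$scatter), spearman_rho = x$spearman_rho,
         strictly_monotone = x$strictly_monotone)
}

#' @rdname tidiers
#' @export
tidy.xdf_study <- function(x, ...) {
  purrr::map(x$records, tidy) |> purrr::list_rbind()
}

#' @rdname tidiers
#' @export
glance.xdf_study <- function(x, ...) glance(x$correlation)

#' Combined per-material summary CSV
#'
#' Writes one row per material:
#' `material,mcl_um,neg_log_D_low,neg_log_D_high,ratio,xi_w_low_um,xi_w_high_um`.
#'
#' @param study An `xdf_study`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_study_csv <- function(study, path) {
  stopifnot(inherits(study, "xdf_study"))
  wide <- tidy(study) |>
    dplyr::select("material", "mcl_um", "ratio_low_over_high", "bin",
                  "neg_log_D", "xi_w_um") |>
    tidyr::pivot_wider(names_from = "bin",
                       values_from = c("neg_log_D", "xi_w_um")) |>
    dplyr::rename(ratio = "ratio_low_over_high",
                  xi_w_low_um = "xi_w_um_low", xi_w_high_um = "xi_w_um_high")
  utils::write.csv(wide, path, row.names = FALSE)
  invisible(path)
}
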