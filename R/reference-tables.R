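#' Reference TCGA splicing-module tables
#'
#' Two small reference tables from the TCGA pan-cancer splicing-module
#' analysis ship with the package as plain TSV:
#' `tcga_module_census()` lists the 51 modules identified across 16
#' cancer types with per-module gene and event counts and the
#' splice-class breakdown (AA, AD, AT, ES, ME, RI);
#' `tcga_module_prognosis()` lists the modules tested against overall
#' survival (OS) and progression-free interval (PFI) with hazard
#' ratios, 95 percent confidence bounds, and log-rank P-values. They
#' serve as inputs to the module-accounting and significance-retention
#' logic (e.g. [retain_prognostic()]) and as ground truth for census
#' bookkeeping.
#'
#' @return A tibble.
#' @export
tcga_module_census <- function() {
  path <- system.file("extdata", "tcga_module_census.tsv",
                      package = "splicemod", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' @rdname tcga_module_census
#' @export
tcga_module_prognosis <- function() {
  path <- system.file("extdata", "tcga_module_prognosis.tsv",
                      package = "splicemod", mustWork = TRUE)
  as_tibble(read.delim(path, sep = "\t", stringsAsFactors = FALSE))
}

#' Survival-association rows from a printed prognosis table
#'
#' Reshapes a wide per-module prognosis table (as returned by
#' [tcga_module_prognosis()]) into the long `survival_association`
#' layout so the retention logic can be applied to published numbers.
#'
#' @param prognosis Tibble with columns `module`, `os_p`, `pfi_p` (and
#'   optionally the HR/CI columns).
#' @return A `survival_association` tibble.
#' @export
as_survival_association <- function(prognosis) {
  long <- dplyr::bind_rows(
    tibble(module = prognosis$module, endpoint = "OS",
           hr = prognosis$os_hr %||% NA_real_,
           ci_low = prognosis$os_ci_low %||% NA_real_,
           ci_high = prognosis$os_ci_high %||% NA_real_,
           logrank_chisq = NA_real_, logrank_p = prognosis$os_p,
           n_high = NA_integer_, n_low = NA_integer_),
    tibble(module = prognosis$module, endpoint = "PFI",
           hr = prognosis$pfi_hr %||% NA_real_,
           ci_low = prognosis$pfi_ci_low %||% NA_real_,
           ci_high = prognosis$pfi_ci_high %||% NA_real_,
           logrank_chisq = NA_real_, logrank_p = prognosis$pfi_p,
           n_high = NA_integer_, n_low = NA_integer_)
  )
  class(long) <- c("survival_association", class(long))
  long
}
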