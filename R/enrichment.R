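#' Fisher's-exact gene-set over-representation of module genes
#'
#' Tests each gene set for over-representation among a module's genes
#' relative to a background of all quantified spliced genes. The
#' one-sided P is the hypergeometric upper tail
#' `P(X >= k)` for `k` overlap genes out of `n` module genes, with `K`
#' set genes in a background of `N`; q-values are Benjamini-Hochberg
#' across tested terms. Testing is gene-level: a gene with several
#' module events counts once.
#'
#' @param module_genes Character vector of gene symbols (subset of the
#'   background; symbols are uppercased).
#' @param sets Gene sets as returned by [read_gmt()] (named list of
#'   symbol vectors).
#' @param background_genes Character vector, the spliced-gene universe.
#' @return Tibble `term`, `description`, `k`, `K`, `n`, `N`,
#'   `odds_ratio`, `p`, `q`, sorted by `p`. Sets with no background
#'   overlap are skipped. An infinite sample odds ratio is reported as
#'   `Inf`.
#' @export
fisher_enrich <- function(module_genes, sets, background_genes) {
  background <- unique(toupper(background_genes))
  if (length(background) == 0) abort("empty background")
  module <- unique(toupper(module_genes))
  if (!all(module %in% background)) {
    abort("module genes must be a subset of the background")
  }
  n <- length(module)
  N <- length(background)
  rows <- purrr::imap(sets, function(genes, term) {
    set_bg <- intersect(unique(toupper(genes)), background)
    K <- length(set_bg)
    if (K == 0) return(NULL)
    k <- length(intersect(module, set_bg))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    or_num <- k * (N - K - n + k)
    or_den <- (K - k) * (n - k)
    tibble(term = term,
           description = attr(genes, "description") %||% "",
           k = k, K = K, n = n, N = N,
           odds_ratio = if (or_den == 0) Inf else or_num / or_den,
           p = min(1, p))
  })
  out <- dplyr::bind_rows(purrr::compact(rows))
  if (nrow(out) == 0) abort("no gene set overlaps the background")
  out$q <- bh_fdr(out$p)
  dplyr::arrange(out, .data$p, .data$term)
}
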