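#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy and summarise pipeline result objects
#'
#' Broom-style accessors: `tidy()` returns the per-unit table of a result
#' object as a plain tibble; `glance()` returns a one-row summary.
#'
#' @param x An `assoc_tbl`, `genotype_calls`, `embryo_clust`,
#'   `correlation_map` or `window_profile` object.
#' @param ... Ignored.
#' @return A tibble.
#' @name trophreg_tidiers
NULL

#' @rdname trophreg_tidiers
#' @method tidy assoc_tbl
#' @export
tidy.assoc_tbl <- function(x, ...) {
  as_tibble(x)
}

#' @rdname trophreg_tidiers
#' @method glance assoc_tbl
#' @export
glance.assoc_tbl <- function(x, ...) {
  tibble(tf_name = attr(x, "tf_name"), d0 = attr(x, "d0"),
         max_dist = attr(x, "max_dist"), n_genes = nrow(x),
         n_scored = sum(x$score > 0), max_score = max(x$score))
}

#' @rdname trophreg_tidiers
#' @method tidy genotype_calls
#' @export
tidy.genotype_calls <- function(x, ...) {
  as_tibble(x)
}

#' @rdname trophreg_tidiers
#' @method glance genotype_calls
#' @export
glance.genotype_calls <- function(x, ...) {
  tb <- table(x$genotype)
  tibble(n_embryos = nrow(x), n_null = unname(tb["null"]),
         n_het = unname(tb["het"]), n_wt = unname(tb["wt"]),
         n_ambiguous = unname(tb["ambiguous"]),
         negligible_threshold = attr(x, "negligible_threshold"))
}

#' @rdname trophreg_tidiers
#' @method tidy embryo_clust
#' @export
tidy.embryo_clust <- function(x, ...) {
  x$labels
}

#' @rdname trophreg_tidiers
#' @method glance embryo_clust
#' @export
glance.embryo_clust <- function(x, ...) {
  tibble(n_embryos = length(x$hclust$order), k = x$k,
         max_height = max(x$hclust$height))
}

#' @rdname trophreg_tidiers
#' @method tidy correlation_map
#' @export
tidy.correlation_map <- function(x, ...) {
  as_tibble(x)
}

#' @rdname trophreg_tidiers
#' @method glance correlation_map
#' @export
glance.correlation_map <- function(x, ...) {
  tb <- table(x$cluster)
  tibble(anchor = attr(x, "anchor"), tau = attr(x, "tau"),
         method = attr(x, "method"), n_genes = nrow(x),
         n_cluster1 = unname(tb["1"]), n_cluster2 = unname(tb["2"]),
         n_cluster3 = unname(tb["3"]))
}

#' @rdname trophreg_tidiers
#' @method tidy window_profile
#' @export
tidy.window_profile <- function(x, ...) {
  as_tibble(x)
}
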