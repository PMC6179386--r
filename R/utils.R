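#' @importFrom rlang .data
#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

# deterministic per-stage seed derived from a single master seed; kept
# inside 32-bit integer range
derive_seed <- function(master, stage) {
  as.integer((as.numeric(master) %% 65536 * 31907 + stage * 9973) %%
               2147483647)
}
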