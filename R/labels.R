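#' Tissue label codes used by the synthetic ground-truth volumes
#'
#' Integer codes for the label volumes produced by the generators:
#' `background` (0), `marrow` (1), `trabecular` (2), `cortical` (3),
#' `implant` (4), `cavity` (5, broached void before implantation). Phantom
#' insert `k` is coded `insert_base + k` (11, 12, ...).
#'
#' @format A named list of integer codes.
#' @export
tissue_labels <- list(
  background = 0L,
  marrow     = 1L,
  trabecular = 2L,
  cortical   = 3L,
  implant    = 4L,
  cavity     = 5L,
  insert_base = 10L
)

#' Labels counted as bone for mass bookkeeping and BV/TV
#' @return Integer vector of label codes.
#' @export
bone_labels <- function() c(tissue_labels$trabecular, tissue_labels$cortical)
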