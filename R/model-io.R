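# ---------------------------------------------------------------------------
# Model checkpointing: native R serialisation with an embedded config/seed.
# ---------------------------------------------------------------------------

#' Save a model checkpoint
#'
#' Serialises the module tree together with metadata (an embedded copy of
#' the configuration where available, and the recorded seed).
#'
#' @param model a module tree.
#' @param path output file (.rds).
#' @param seed the seed the weights were drawn with (recorded in the file).
#' @return \code{path}, invisibly.
#' @export
save_model <- function(model, path, seed = NA_integer_) {
  cfg <- NULL
  if (model$kind == "csat_backbone") cfg <- model$cfg$config
  if (model$kind == "backbone_with_head")
    cfg <- model$children$backbone$cfg$config
  saveRDS(list(model = model, config = cfg, seed = seed,
               package_version = as.character(utils::packageVersion("rckd"))),
          path)
  invisible(path)
}

#' Load a model checkpoint
#'
#' @param path file written by [save_model()].
#' @return list with \code{model}, \code{config}, \code{seed}.
#' @export
load_model <- function(path) readRDS(path)
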