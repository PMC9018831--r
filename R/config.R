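#' @include synthetic.R
NULL

.featureSets <- list(
  "13-epi" = c("ATAC-seq", "CTCF", "H3K4me1", "H3K4me2", "H3K4me3", "H3K9ac",
               "H3K9me3", "H3K27ac", "H3K27me3", "H3K36me3", "H3K79me2",
               "Nanog", "Rad21"),
  "7-epi" = c("ATAC-seq", "CTCF", "H3K4me1", "H3K4me2", "H3K4me3",
              "H3K27ac", "H3K27me3"),
  "6-epi" = c("ATAC-seq", "CTCF", "H3K4me1", "H3K4me3", "H3K27ac",
              "H3K27me3"),
  "3-epi" = c("ATAC-seq", "CTCF", "H3K27ac")
)

#' Named epigenomic feature sets
#'
#' Returns one of the standard feature panels by common availability; the
#' 6-epi set is the recommended default.  DNase-seq is accepted as an alias
#' wherever ATAC-seq is requested (chromatin-accessibility substitute).
#'
#' @param name "13-epi", "7-epi", "6-epi" or "3-epi".
#' @return character vector of feature names.
#' @export
epiFeatureSet <- function(name = "6-epi") {
  if (!name %in% names(.featureSets))
    stop("unknown feature set '", name, "'; available: ",
         paste(names(.featureSets), collapse = ", "))
  .featureSets[[name]]
}

#' Canonicalize a feature name
#'
#' Maps aliases (DNase-seq for ATAC-seq) onto the canonical feature names.
#'
#' @param x character vector of feature names.
#' @return canonicalized names.
#' @export
canonicalFeature <- function(x) {
  ifelse(x %in% c("DNase-seq", "DNase"), "ATAC-seq", x)
}

.knownKeys <- c("features", "feature_set", "window_bp", "step_bp", "band_bp",
                "seed", "model", "caller", "io")
.modelKeys <- c("conv_channels", "conv_kernels", "gcn_units", "embed_dim",
                "encoding_dim", "lr", "epochs_loop", "epochs_profile",
                "freeze_trunk_phase1")
.callerKeys <- c("fdr", "loop_fold", "stripe_fold", "radius", "core",
                 "min_loop_distance_bp", "max_loop_distance_bp",
                 "min_stripe_length_px", "stripe_flank")

#' Load and validate a run configuration
#'
#' Reads a YAML configuration, rejects unknown keys by name, fills defaults
#' (250-kb window, 50-kb step, 200-kb band, the 6-epi feature set), and
#' echoes the resolved configuration as a JSON log line.
#'
#' @param path YAML file, or NULL for an all-defaults configuration.
#' @param requireSeed error when no seed is set (stochastic commands).
#' @param quiet suppress the resolved-config log line.
#' @return a \linkS4class{RunConfig}.
#' @export
validateConfig <- function(path = NULL, requireSeed = FALSE, quiet = FALSE) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), .knownKeys)
  if (length(unknown))
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
  if (!is.null(raw$model)) {
    um <- setdiff(names(raw$model), .modelKeys)
    if (length(um)) stop("unknown model key(s): ", paste(um, collapse = ", "))
  }
  if (!is.null(raw$caller)) {
    uc <- setdiff(names(raw$caller), .callerKeys)
    if (length(uc)) stop("unknown caller key(s): ", paste(uc, collapse = ", "))
  }
  features <- if (!is.null(raw$features)) canonicalFeature(unlist(raw$features))
    else epiFeatureSet(if (is.null(raw$feature_set)) "6-epi" else raw$feature_set)
  known <- unique(unlist(.featureSets))
  bad <- setdiff(features, known)
  if (length(bad))
    stop("unknown feature(s): ", paste(bad, collapse = ", "),
         "; known features: ", paste(known, collapse = ", "))
  model <- utils::modifyList(list(
    conv_channels = c(32, 64), conv_kernels = c(11, 5), gcn_units = c(64, 64),
    embed_dim = 64, encoding_dim = 8, lr = 1e-3, epochs_loop = 40,
    epochs_profile = 25, freeze_trunk_phase1 = FALSE),
    if (is.null(raw$model)) list() else raw$model)
  caller <- utils::modifyList(list(
    fdr = 0.1, loop_fold = 1.75, stripe_fold = 2, radius = 5, core = 2,
    min_loop_distance_bp = 10000, max_loop_distance_bp = 200000,
    min_stripe_length_px = 10, stripe_flank = 3),
    if (is.null(raw$caller)) list() else raw$caller)
  seed <- if (is.null(raw$seed)) NA_real_ else as.numeric(raw$seed)
  if (requireSeed && is.na(seed))
    stop("a seed is required for stochastic commands; set 'seed' in the config")
  cfg <- new("RunConfig",
             features = features,
             windowBp = if (is.null(raw$window_bp)) 250000 else raw$window_bp,
             stepBp = if (is.null(raw$step_bp)) 50000 else raw$step_bp,
             bandBp = if (is.null(raw$band_bp)) 200000 else raw$band_bp,
             model = model, caller = caller, seed = seed)
  if (!quiet) logEvent("config_resolved", features = cfg@features,
                       window_bp = cfg@windowBp, step_bp = cfg@stepBp,
                       band_bp = cfg@bandBp, seed = seed)
  cfg
}

#' Emit a structured JSON log line
#'
#' @param event short event name.
#' @param ... named fields to log.
#' @return invisibly, the JSON string.
#' @export
logEvent <- function(event, ...) {
  line <- jsonlite::toJSON(c(list(event = event), list(...)),
                           auto_unbox = TRUE, digits = NA)
  message(line)
  invisible(as.character(line))
}
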