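#' Pipeline configuration
#'
#' Central collection of the tunable parameters of the maturation,
#' classification, segmentation and genome-assignment rules. Values not
#' supplied keep their defaults; unknown names are an error.
#'
#' @param ... named parameter overrides. Recognized names:
#' \describe{
#'   \item{signatureSet}{known mature-start signatures searched during
#'     signal-peptide trimming. Defaults cover the omega-1,2 starts (ARE,
#'     ARQ, KEL), omega-5 starts (SRL, GRL), the alpha start VRV, gamma
#'     starts NMQ/NIQ, and the LMW-GS starts ISQ, SHI and MET.}
#'   \item{maxSignatureOffset}{how deep into the precursor (residues) a
#'     mature-start signature is searched for; default 40, comfortably
#'     beyond the ~20-residue gliadin signal peptides.}
#'   \item{omegaMotifs}{repeat motifs diagnostic of omega-gliadins
#'     (PQQPFP for omega-1,2; FPQQQ and QQIPQQ for omega-5).}
#'   \item{omegaDensityThreshold}{minimum fraction of the mature sequence
#'     covered by omega motifs for the omega call; default 0.30.}
#'   \item{omegaMaxCys}{maximum cysteine count compatible with omega
#'     (default 1: most omega-gliadins have none, rare variants one).}
#'   \item{gammaMinRepeats}{minimum count of the degenerate gamma repeat
#'     for the gamma call (default 5).}
#'   \item{gammaCys, alphaCys, cysTol}{expected cysteine counts (8 and 6)
#'     and the tolerance (1) admitting the observed 9-Cys gamma and 7-Cys
#'     alpha variants.}
#'   \item{alphaMotifs, alphaMinRepeats, alphaSignatures}{alpha repeat
#'     motifs (PQPQLPY, PFPQPQ), their minimum count (3), and accepted
#'     alpha mature-start signatures (VRV).}
#'   \item{segMaxGap}{segmentation: spacer gap (residues) bridged when
#'     merging motif occurrences into a repetitive domain; default 6.}
#'   \item{segMinRepLen}{minimum length of a repetitive segment; default 10.}
#'   \item{maxSigPrefix}{a prefix up to this long (default 12) before the
#'     first repetitive domain is labeled as the N-terminal signature.}
#'   \item{polyQMinLen}{minimum polyglutamine run length; default 6.}
#'   \item{deamidationMode}{`"native_only"` or `"both"`.}
#'   \item{tieMargin}{identity-point margin below which two best references
#'     from different genomes give an `unknown` call; default 0.5.}
#'   \item{alignMatch, alignMismatch, alignGap}{global-alignment scoring
#'     for percent identity (1 / 0 / 1, i.e. identity scoring with a linear
#'     gap penalty).}
#' }
#' @return named list of parameters (class `gliadinConfig`).
#' @examples
#' cfg <- profilerConfig(gammaMinRepeats = 4)
#' @export
profilerConfig <- function(...) {
  defaults <- list(
    signatureSet = c("ARE", "ARQ", "KEL", "SRL", "GRL", "VRV",
                     "ISQ", "SHI", "MET", "NMQ", "NIQ"),
    maxSignatureOffset = 40L,
    omegaMotifs = c("PQQPFP", "FPQQQ", "QQIPQQ"),
    omegaDensityThreshold = 0.30,
    omegaMaxCys = 1L,
    gammaMinRepeats = 5L,
    gammaCys = 8L,
    alphaCys = 6L,
    cysTol = 1L,
    alphaMotifs = c("PQPQLPY", "PFPQPQ"),
    alphaMinRepeats = 3L,
    alphaSignatures = "VRV",
    segMaxGap = 6L,
    segMinRepLen = 10L,
    maxSigPrefix = 12L,
    polyQMinLen = 6L,
    deamidationMode = "native_only",
    tieMargin = 0.5,
    alignMatch = 1,
    alignMismatch = 0,
    alignGap = 1)
  override <- list(...)
  if (length(override)) {
    bad <- setdiff(names(override), names(defaults))
    if (length(bad) || is.null(names(override)) || any(!nzchar(names(override))))
      stop("unknown configuration parameter(s): ",
           paste(bad, collapse = ", "))
    defaults <- modifyList(defaults, override)
  }
  stopifnot(defaults$omegaDensityThreshold > 0,
            defaults$omegaDensityThreshold <= 1,
            defaults$polyQMinLen >= 2,
            defaults$tieMargin >= 0,
            defaults$deamidationMode %in% c("native_only", "both"))
  structure(defaults, class = "gliadinConfig")
}

#' Read a pipeline configuration file
#'
#' YAML file whose keys mirror the arguments of [profilerConfig()]; values
#' given in the file override the defaults.
#'
#' @param path path to a YAML file.
#' @return the merged configuration (see [profilerConfig()]).
#' @export
readPipelineConfig <- function(path) {
  if (!file.exists(path))
    stop("configuration file not found: ", path)
  vals <- yaml::read_yaml(path)
  if (is.null(vals)) vals <- list()
  do.call(profilerConfig, vals)
}
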