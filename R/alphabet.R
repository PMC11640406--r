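#' The Cardioish symbol alphabet
#'
#' The 12 three-character symbols naming the standard ECG leads, in the
#' fixed order used throughout the package: limb leads I-III (`Ld1`-`Ld3`),
#' augmented leads (`AVR`, `AVL`, `AVF`) and precordial leads V1-V6
#' (`V1S`, `V2S`, `V3A`, `V4A`, `V5L`, `V6L` -- the trailing letter tags
#' the cardiac region the lead views: Septal, Anterior, Lateral). Feature
#' index decoding, sentences and connectome graphs all use this order, so
#' symbol `k` always means lead `k` of a beat matrix.
#'
#' @return Character vector of 12 distinct 3-character symbols.
#' @seealso [lead_names()] for the conventional clinical lead labels.
#' @export
#' @examples
#' cardioish_alphabet()
cardioish_alphabet <- function() {
  c("Ld1", "Ld2", "Ld3", "AVR", "AVL", "AVF",
    "V1S", "V2S", "V3A", "V4A", "V5L", "V6L")
}

#' Conventional 12-lead ECG lead names
#'
#' @return Character vector of the 12 standard lead labels, in the same
#'   order as [cardioish_alphabet()].
#' @export
lead_names <- function() {
  c("I", "II", "III", "aVR", "aVL", "aVF",
    "V1", "V2", "V3", "V4", "V5", "V6")
}

# number of leads; fixed by the 12-lead ECG standard and the alphabet
N_LEADS <- 12L
N_FEATURES <- 144L
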