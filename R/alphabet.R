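#' @importFrom stats pt rbinom rgeom runif setNames t.test rlnorm
#' @importFrom utils read.delim write.table
NULL

#' Amino-acid alphabet and PTM/residue compatibility
#'
#' `AA_STANDARD` is the 20-letter standard amino-acid alphabet; sequences may
#' additionally contain `X` (unknown residue). `PTM_RESIDUES` maps each
#' supported modification type to the one-letter code of the residue it
#' modifies: phosphorylation of Ser/Thr/Tyr, O-linked glycosylation of
#' (hydroxy)proline, N-linked glycosylation of Asn, acetylation of Lys and
#' methylation of Lys or Arg.
#'
#' @format `AA_STANDARD` is a length-20 character vector; `PTM_RESIDUES` a
#'   named character vector keyed by PTM type.
#' @export
AA_STANDARD <- c("A","C","D","E","F","G","H","I","K","L",
                 "M","N","P","Q","R","S","T","V","W","Y")

#' @rdname AA_STANDARD
#' @export
PTM_RESIDUES <- c(
  "pSer"  = "S",
  "pThr"  = "T",
  "pTyr"  = "Y",
  "O-gly" = "P",
  "N-gly" = "N",
  "K-ace" = "K",
  "K-met" = "K",
  "R-met" = "R"
)

#' PTM types recognised by the pipeline
#' @rdname AA_STANDARD
#' @export
PTM_TYPES <- names(PTM_RESIDUES)

valid_categories <- c("monocot", "dicot", "unspecified")
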