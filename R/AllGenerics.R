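#' Split a pedigree into per-family pedigrees
#'
#' @param x a \linkS4class{Pedigree}.
#' @return Named list of single-family \linkS4class{Pedigree} objects.
#' @export
setGeneric("families", function(x) standardGeneric("families"))

#' Pedigree members as a data.frame
#'
#' @param x a \linkS4class{Pedigree}.
#' @return data.frame with one row per individual.
#' @export
setGeneric("members", function(x) standardGeneric("members"))

#' Ids of affected individuals
#'
#' @param x a \linkS4class{Pedigree}.
#' @return Character vector of individual ids with affection status
#'   `"affected"`.
#' @export
setGeneric("affectedIds", function(x) standardGeneric("affectedIds"))
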