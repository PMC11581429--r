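#' Read a 6-column PED pedigree file
#'
#' Reads the whitespace-delimited PED dialect (family id, individual id,
#' father id, mother id, sex, phenotype). Codes follow the usual convention:
#' sex 1 = male, 2 = female, anything else unknown; phenotype 2 = affected,
#' 1 = unaffected, 0/-9 = unknown; a parent id of "0" means the parent is not
#' in the pedigree.
#'
#' @param path path to a PED file.
#' @return A \linkS4class{Pedigree} holding every family in the file.
#' @examples
#' ped <- tempfile(fileext = ".ped")
#' writeLines(c("F1 dad 0 0 1 1", "F1 mum 0 0 2 1",
#'              "F1 kid dad mum 1 2"), ped)
#' readPedigree(ped)
#' @export
readPedigree <- function(path) {
  if (!file.exists(path)) stop("pedigree file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  lines <- lines[!startsWith(trimws(lines), "#")]
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 6))
    stop("malformed PED row (expected 6 columns) at line ",
         which(nf != 6)[1], ": '", lines[which(nf != 6)[1]], "'")
  m <- as.data.frame(do.call(rbind, fields), stringsAsFactors = FALSE)
  names(m) <- c("family_id", "individual_id", "father_id", "mother_id",
                "sex", "affected")
  m$father_id[m$father_id == "0"] <- NA_character_
  m$mother_id[m$mother_id == "0"] <- NA_character_
  m$sex <- c("1" = "male", "2" = "female")[m$sex]
  m$sex[is.na(m$sex)] <- "unknown"
  m$affected <- c("2" = "affected", "1" = "unaffected")[m$affected]
  m$affected[is.na(m$affected)] <- "unknown"
  new("Pedigree", members = m)
}

#' Write a pedigree back to PED format
#'
#' Inverse of [readPedigree()]; missing parents are written as "0".
#'
#' @param ped a \linkS4class{Pedigree}.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePedigree <- function(ped, path) {
  m <- members(ped)
  out <- data.frame(
    m$family_id, m$individual_id,
    ifelse(is.na(m$father_id), "0", m$father_id),
    ifelse(is.na(m$mother_id), "0", m$mother_id),
    c(male = "1", female = "2", unknown = "0")[m$sex],
    c(affected = "2", unaffected = "1", unknown = "0")[m$affected])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname families
#' @export
setMethod("families", "Pedigree", function(x) {
  m <- x@members
  lapply(split(m, m$family_id), function(fm) {
    rownames(fm) <- NULL
    new("Pedigree", members = fm)
  })
})

#' @rdname members
#' @export
setMethod("members", "Pedigree", function(x) x@members)

#' @rdname affectedIds
#' @export
setMethod("affectedIds", "Pedigree", function(x)
  x@members$individual_id[x@members$affected == "affected"])

setMethod("show", "Pedigree", function(object) {
  m <- object@members
  cat("Pedigree:", length(unique(m$family_id)), "family(ies),",
      nrow(m), "individuals (",
      sum(m$affected == "affected"), "affected )\n")
  invisible(NULL)
})
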