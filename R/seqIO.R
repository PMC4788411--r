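#' @importFrom Biostrings readDNAStringSet writeXStringSet DNAString
#'   reverseComplement
NULL

#' Read / write CDS FASTA
#'
#' Thin wrappers around Biostrings FASTA I/O enforcing the package's
#' sequence contract: ids must be unique, sequences are upper-cased on
#' read, and files are wrapped at 60 columns on write.
#'
#' @param path FASTA file.
#' @return \code{readFastaCds}: named uppercase character vector.
#' @export
readFastaCds <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(dss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ",
      paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  setNames(toupper(as.character(dss)), ids)
}

#' @rdname readFastaCds
#' @param x named character vector or \code{DNAStringSet}.
#' @return \code{writeFastaCds}: the path, invisibly.
#' @export
writeFastaCds <- function(x, path) {
  if (is.character(x)) x <- Biostrings::DNAStringSet(toupper(x))
  if (is.null(names(x)) || anyDuplicated(names(x)))
    stop("records must carry unique ids", call. = FALSE)
  Biostrings::writeXStringSet(x, path, width = 60L)
  invisible(path)
}

# GenBank 1-based inclusive coordinates <-> 0-based half-open.
gbToZeroBased <- function(start, end) cbind(start = start - 1L, end = end)
zeroBasedToGb <- function(start, end) cbind(start = start + 1L, end = end)

# --- GenBank flat-file parsing -------------------------------------------
# No installed R package parses GenBank feature tables, so the flat-file
# reader lives here: LOCUS line, FEATURES block (keys at column 6,
# continuations/qualifiers at column 22), ORIGIN sequence block.

#' Parse a GenBank flat file
#'
#' Reads a single-record GenBank flat file: the LOCUS name, the full
#' ORIGIN sequence, and the feature table with location strings and
#' qualifiers.  Location strings may use \code{join()}, \code{order()},
#' \code{complement()} (possibly nested) and partial-end markers
#' (\code{<}, \code{>}), which are stripped.
#'
#' @param path GenBank flat file (text).
#' @return list with \code{name}, \code{length}, \code{sequence}
#'   (uppercase), and \code{features}: a data.frame with columns
#'   \code{key}, \code{location}, \code{gene}, \code{pseudo}.
#' @export
readGenBank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file: ", path, call. = FALSE)
  name <- strsplit(trimws(sub("^LOCUS\\s+", "", lines[1])), "\\s+")[[1]][1]
  fStart <- grep("^FEATURES", lines)
  oStart <- grep("^ORIGIN", lines)
  if (length(fStart) != 1L || length(oStart) != 1L)
    stop("GenBank record must contain one FEATURES and one ORIGIN block",
      call. = FALSE)
  seqLines <- lines[(oStart + 1L):length(lines)]
  seqLines <- seqLines[!grepl("^//", seqLines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))

  featLines <- lines[(fStart + 1L):(oStart - 1L)]
  feats <- list()
  cur <- NULL
  inLocation <- FALSE
  for (ln in featLines) {
    if (grepl("^ {5}\\S", ln)) {
      if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur
      parts <- strsplit(trimws(ln), "\\s+")[[1]]
      cur <- list(key = parts[1],
        location = paste(parts[-1], collapse = ""),
        quals = character(0))
      inLocation <- TRUE
    } else if (!is.null(cur)) {
      txt <- trimws(ln)
      if (startsWith(txt, "/")) {
        cur$quals <- c(cur$quals, txt)
        inLocation <- FALSE
      } else if (inLocation) {
        cur$location <- paste0(cur$location, txt)
      } else if (length(cur$quals)) {
        # continuation of a (possibly quoted) qualifier value
        cur$quals[length(cur$quals)] <-
          paste(cur$quals[length(cur$quals)], txt)
      }
    }
  }
  if (!is.null(cur)) feats[[length(feats) + 1L]] <- cur

  getQual <- function(quals, what) {
    hit <- grep(paste0("^/", what, "="), quals, value = TRUE)
    if (!length(hit)) return(NA_character_)
    gsub("^\"|\"$", "", sub(paste0("^/", what, "="), "", hit[1]))
  }
  features <- data.frame(
    key = vapply(feats, `[[`, character(1), "key"),
    location = vapply(feats, `[[`, character(1), "location"),
    gene = vapply(feats, function(f) getQual(f$quals, "gene"), character(1)),
    pseudo = vapply(feats, function(f) any(f$quals == "/pseudo"),
      logical(1)),
    stringsAsFactors = FALSE)
  list(name = name, length = nchar(sequence), sequence = sequence,
    features = features)
}

# Recursive location-string resolver: returns the spliced,
# strand-resolved sequence for a GenBank location.
resolveLocation <- function(loc, sequence) {
  loc <- gsub("\\s", "", loc)
  if (grepl("^complement\\(", loc)) {
    inner <- sub("^complement\\((.*)\\)$", "\\1", loc)
    s <- resolveLocation(inner, sequence)
    return(as.character(
      Biostrings::reverseComplement(Biostrings::DNAString(s))))
  }
  if (grepl("^(join|order)\\(", loc)) {
    inner <- sub("^(join|order)\\((.*)\\)$", "\\2", loc)
    parts <- character(0)
    depth <- 0L; start <- 1L
    chars <- strsplit(inner, "")[[1]]
    for (i in seq_along(chars)) {
      ch <- chars[i]
      if (ch == "(") depth <- depth + 1L
      if (ch == ")") depth <- depth - 1L
      if (ch == "," && depth == 0L) {
        parts <- c(parts, substr(inner, start, i - 1L))
        start <- i + 1L
      }
    }
    parts <- c(parts, substr(inner, start, nchar(inner)))
    return(paste0(vapply(parts, resolveLocation, character(1),
      sequence = sequence), collapse = ""))
  }
  loc <- gsub("[<>]", "", loc)
  if (grepl("^\\d+\\.\\.\\d+$", loc)) {
    se <- as.integer(strsplit(loc, "\\.\\.")[[1]])
  } else if (grepl("^\\d+$", loc)) {
    se <- rep(as.integer(loc), 2L)
  } else {
    stop("unsupported location element: ", loc, call. = FALSE)
  }
  if (se[1] > se[2] || se[2] > nchar(sequence))
    stop("location out of bounds: ", loc, call. = FALSE)
  z <- gbToZeroBased(se[1], se[2])          # 0-based half-open internally
  substr(sequence, z[, "start"] + 1L, z[, "end"])
}

#' Extract CDS sequences from a plastome GenBank record
#'
#' Splices and strand-resolves every CDS feature of a GenBank record and
#' applies an extraction policy; rejected features are logged with a
#' reason, never fatal.  Inverted-repeat duplicates (same gene name and
#' identical sequence as an already-accepted CDS) are counted once by
#' default so they do not double-weight a downstream usage table.
#'
#' @param genbank a file path or the list returned by
#'   \code{\link{readGenBank}}.
#' @param requireMod3 reject CDS whose length is not a multiple of 3.
#' @param allowInternalStops keep CDS with in-frame internal stops.
#' @param dedupeInvertedRepeat drop exact gene-name + sequence
#'   duplicates.
#' @param minLengthCodons minimum CDS length in codons (>= 2).
#' @param excludePseudo drop features carrying \code{/pseudo}.
#' @param codeId translation table for the internal-stop check.
#' @return list with \code{cds} (named character vector; names are gene
#'   names, made unique) and \code{report} (data.frame: \code{feature},
#'   \code{gene}, \code{location}, \code{length_nt}, \code{status},
#'   \code{reason}).
#' @export
extractCds <- function(genbank, requireMod3 = TRUE,
    allowInternalStops = FALSE, dedupeInvertedRepeat = TRUE,
    minLengthCodons = 2L, excludePseudo = TRUE, codeId = "11") {
  if (is.character(genbank) && length(genbank) == 1L)
    genbank <- readGenBank(genbank)
  if (minLengthCodons < 2L)
    stop("minLengthCodons must be >= 2", call. = FALSE)
  feats <- genbank$features
  idx <- which(feats$key == "CDS")
  code <- geneticCodeMap(codeId)
  accepted <- character(0)
  rows <- list()
  seen <- character(0)
  for (k in idx) {
    gene <- feats$gene[k]
    if (is.na(gene)) gene <- paste0("cds_", k)
    status <- "accepted"; reason <- ""
    s <- tryCatch(resolveLocation(feats$location[k], genbank$sequence),
      error = function(e) e)
    if (inherits(s, "error")) {
      status <- "rejected"; reason <- conditionMessage(s); s <- ""
    } else if (feats$pseudo[k] && excludePseudo) {
      status <- "rejected"; reason <- "pseudo gene"
    } else if (requireMod3 && nchar(s) %% 3L != 0L) {
      status <- "rejected"; reason <- "length not a multiple of 3"
    } else if (nchar(s) < 3L * minLengthCodons) {
      status <- "rejected"; reason <- "shorter than minimum length"
    } else if (grepl("[^ACGT]", s)) {
      status <- "rejected"; reason <- "ambiguous nucleotide"
    } else if (!allowInternalStops && nchar(s) %% 3L == 0L) {
      cods <- splitCodons(s)
      if (length(cods) > 1L && any(code[cods[-length(cods)]] == "*")) {
        status <- "rejected"; reason <- "internal stop codon"
      }
    }
    if (status == "accepted" && dedupeInvertedRepeat) {
      sig <- paste0(gene, "|", s)
      if (sig %in% seen) {
        status <- "rejected"; reason <- "inverted-repeat duplicate"
      } else {
        seen <- c(seen, sig)
      }
    }
    if (status == "accepted") {
      nm <- make.unique(c(names(accepted), gene))[length(accepted) + 1L]
      accepted[nm] <- s
    }
    rows[[length(rows) + 1L]] <- data.frame(feature = k, gene = gene,
      location = feats$location[k], length_nt = nchar(s),
      status = status, reason = reason, stringsAsFactors = FALSE)
  }
  report <- if (length(rows))
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else
    data.frame(feature = integer(0), gene = character(0),
      location = character(0), length_nt = integer(0),
      status = character(0), reason = character(0))
  list(cds = accepted, report = report)
}

#' Write a CDS extraction report as TSV
#'
#' @param extraction result of \code{\link{extractCds}}.
#' @param path output file.
#' @return the path, invisibly.
#' @export
writeExtractionReport <- function(extraction, path) {
  write.table(extraction$report, path, sep = "\t", quote = FALSE,
    row.names = FALSE)
  invisible(path)
}
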