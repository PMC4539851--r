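#' Parse a GenBank flat file into an annotation
#'
#' Reads the feature table of a GenBank flat file (multi-record files are
#' allowed, one record per replicon; the ORIGIN sequence is ignored) and
#' returns one gene record per CDS, tRNA, rRNA or ncRNA feature.
#' `complement(...)` locations set strand `-`; `join(...)`/`order(...)`
#' locations mark the gene discontiguous and retain the segments; partial
#' markers (`<`, `>`) are stripped, since partiality is not modelled. A
#' `/pseudo` or `/pseudogene` qualifier sets `is_pseudo`; a qualifier or note
#' containing "frameshift" (case-insensitive) sets `is_frameshifted`.
#' Bare `gene` features (and any other feature key) are skipped: only the four
#' counted types enter the model. The number of skipped features is kept in
#' the `skipped_features` attribute of the returned object.
#'
#' @param source path to a GenBank file, or a character vector of its lines.
#' @param label annotation method label attached to the result.
#' @param is_reference whether this annotation is the designated reference.
#' @param patterns product pattern list for [classify_product()].
#' @return An [annotation] object.
#' @examples
#' ann <- generate_annotation(5, replicon_length = 20000, seed = 1)
#' path <- tempfile(fileext = ".gbk")
#' write_genbank(ann, path)
#' parse_genbank(path, label = "truth")
#' @export
parse_genbank <- function(source, label, is_reference = FALSE,
                          patterns = default_product_patterns()) {
  if (length(source) == 1L && !grepl("\n", source)) {
    if (!file.exists(source)) stop("cannot read GenBank file: ", source)
    lines <- readLines(source, warn = FALSE)
  } else {
    lines <- unlist(strsplit(source, "\n", fixed = TRUE))
  }
  if (!length(lines) || !any(nzchar(trimws(lines))))
    stop("empty file: no GenBank records found")

  locus_at <- grep("^LOCUS ", lines)
  if (!length(locus_at))
    stop("no LOCUS line found: not a GenBank flat file")

  genome_name <- "genome"
  def_at <- grep("^DEFINITION ", lines)
  if (length(def_at))
    genome_name <- sub("\\.$", "", trimws(sub("^DEFINITION", "", lines[def_at[1]])))

  record_end <- c(locus_at[-1] - 1L, length(lines))
  rows <- list()
  seg_list <- list()
  replen <- integer(0)
  skipped <- 0L

  for (r in seq_along(locus_at)) {
    block <- lines[locus_at[r]:record_end[r]]
    locus_fields <- strsplit(trimws(block[1]), "[[:space:]]+")[[1]]
    replicon <- locus_fields[2]
    if (is.na(replicon)) stop("malformed LOCUS line: ", block[1])
    len <- suppressWarnings(as.integer(locus_fields[3]))
    if (!is.na(len)) replen[replicon] <- len

    feat_start <- grep("^FEATURES", block)
    if (!length(feat_start)) next
    stop_at <- grep("^(ORIGIN|CONTIG|BASE COUNT|//)", block)
    stop_at <- stop_at[stop_at > feat_start[1]]
    feat_end <- if (length(stop_at)) min(stop_at) - 1L else length(block)
    ftab <- block[seq(feat_start[1] + 1L, length.out = max(0L, feat_end - feat_start[1]))]
    if (!length(ftab)) next

    # feature keys start at column 6; qualifiers/continuations at column 22
    key_idx <- grep("^ {5}\\S", ftab)
    if (!length(key_idx)) next
    for (k in seq_along(key_idx)) {
      from <- key_idx[k]
      to <- if (k < length(key_idx)) key_idx[k + 1] - 1L else length(ftab)
      chunk <- ftab[from:to]
      key <- sub("^ *(\\S+).*$", "\\1", chunk[1])
      if (!key %in% c("CDS", "tRNA", "rRNA", "ncRNA")) {
        skipped <- skipped + 1L
        next
      }
      body <- trimws(substring(chunk, 22))
      # location = leading lines up to the first qualifier
      qual_at <- grep("^/", body)
      loc_end <- if (length(qual_at)) qual_at[1] - 1L else length(body)
      location <- paste(body[seq_len(loc_end)], collapse = "")
      loc <- parse_location(location, feature = sprintf("%s at '%s'", key, location))

      quals <- parse_qualifiers(body[seq(loc_end + 1L, length.out = length(body) - loc_end)])
      note <- quals[["note"]]
      pseudo <- any(names(quals) %in% c("pseudo", "pseudogene"))
      fs_text <- paste(unlist(quals), collapse = " ")
      rows[[length(rows) + 1L]] <- data.frame(
        replicon_id = replicon, feature_type = key, strand = loc$strand,
        start = loc$start, stop = loc$stop,
        locus_tag = quals[["locus_tag"]] %||% NA_character_,
        gene_symbol = quals[["gene"]] %||% NA_character_,
        product = quals[["product"]] %||% NA_character_,
        note = note %||% NA_character_,
        is_pseudo = pseudo,
        is_frameshifted = grepl("frameshift", fs_text, ignore.case = TRUE),
        stringsAsFactors = FALSE)
      seg_list[[length(seg_list) + 1L]] <- loc$segments
    }
  }

  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(replicon_id = character(0), feature_type = character(0),
               strand = character(0), start = integer(0), stop = integer(0))
  if (length(rows)) genes$segments <- seg_list
  ann <- annotation(genes, label = label, genome_name = genome_name,
                    is_reference = is_reference,
                    replicon_lengths = if (length(replen)) replen else NULL,
                    patterns = patterns)
  attr(ann, "skipped_features") <- skipped
  ann
}

# parse a GenBank location string into strand + integer segments
parse_location <- function(loc, feature = loc) {
  s <- gsub("[[:space:]<>]", "", loc)
  strand <- "+"
  if (grepl("complement", s, fixed = TRUE)) strand <- "-"
  s <- gsub("complement\\(|join\\(|order\\(", "", s)
  s <- gsub(")", "", s, fixed = TRUE)
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  if (!length(parts)) stop("malformed location in feature ", feature)
  seg <- lapply(parts, function(p) {
    if (grepl("^[0-9]+\\.\\.[0-9]+$", p)) {
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", p)) {
      rep(as.integer(p), 2L)
    } else {
      stop("malformed location in feature ", feature)
    }
  })
  seg <- do.call(rbind, seg)
  # a segment crossing the replicon origin (stop < start) is retained as-is
  # per-end; the outer span uses per-segment order
  swapped <- seg[, 2] < seg[, 1]
  if (any(swapped)) seg[swapped, ] <- seg[swapped, c(2, 1)]
  colnames(seg) <- c("start", "stop")
  list(strand = strand, segments = seg,
       start = min(seg[, "start"]), stop = max(seg[, "stop"]))
}

# qualifier block -> named character list (flag qualifiers get "")
parse_qualifiers <- function(body) {
  if (!length(body)) return(list())
  qual_at <- grep("^/", body)
  out <- list()
  for (i in seq_along(qual_at)) {
    from <- qual_at[i]
    to <- if (i < length(qual_at)) qual_at[i + 1] - 1L else length(body)
    txt <- paste(body[from:to], collapse = " ")
    m <- regmatches(txt, regexec("^/([A-Za-z_0-9]+)(=(.*))?$", txt))[[1]]
    if (length(m) < 2) next
    name <- m[2]
    val <- if (nzchar(m[3])) gsub('^"|"$', "", m[4]) else ""
    out[[name]] <- val
  }
  out
}
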