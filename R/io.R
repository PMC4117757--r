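## File formats: breakpoint tables (native TSV dialect and BEDPE),
## copy-number segment tables, scenario JSONL, sweep/trajectory TSV.

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("shattersim")),
           error = function(e) "dev")
}

header_comments <- function(...) {
  kv <- list(...)
  kv <- kv[!vapply(kv, is.null, logical(1))]
  c(sprintf("# shattersim %s", pkg_version()),
    if (length(kv)) sprintf("# %s=%s", names(kv),
                            vapply(kv, function(v) paste(format(v), collapse = ","),
                                   character(1))))
}

#' Read a breakpoint table
#'
#' Native dialect: TSV with header columns `pos_low`, `terminus_low`,
#' `pos_high`, `terminus_high` (extra columns such as segment labels are
#' ignored); `#` lines are comments.  A `# L=...` comment, when present,
#' is restored as the `"L"` attribute.
#'
#' @param path File path.
#' @param L Optional chromosome length attached as attribute `"L"`
#'   (overrides any header comment).
#' @return An [breakpoints()] table.
#' @export
read_breakpoints <- function(path, L = NULL) {
  lines <- readLines(path)
  if (is.null(L)) {
    meta <- grep("^# *L=", lines, value = TRUE)
    if (length(meta)) L <- as.numeric(sub("^# *L=", "", meta[1]))
  }
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) stop("no header line found in ", path)
  df <- tryCatch(
    utils::read.table(text = lines[keep], header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE),
    error = function(e) stop("cannot parse ", path, ": ", conditionMessage(e)))
  need <- c("pos_low", "terminus_low", "pos_high", "terminus_high")
  if (!all(need %in% names(df)))
    stop("missing column(s): ", paste(setdiff(need, names(df)), collapse = ", "))
  for (col in c("pos_low", "pos_high")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v)) {
      bad <- which(is.na(v))[1]
      stop(sprintf("line %d: non-numeric %s %s", lineno[bad + 1L], col,
                   dQuote(df[[col]][bad])))
    }
    df[[col]] <- v
  }
  for (col in c("terminus_low", "terminus_high")) {
    badv <- !df[[col]] %in% c("head", "tail")
    if (any(badv)) {
      bad <- which(badv)[1]
      stop(sprintf("line %d: unknown terminus token %s", lineno[bad + 1L],
                   dQuote(df[[col]][bad])))
    }
  }
  bp <- breakpoints(df$pos_low, df$terminus_low, df$pos_high, df$terminus_high)
  attr(bp, "L") <- L
  bp
}

#' Write a breakpoint table
#'
#' @param bp An [breakpoints()] table.
#' @param path Output path.
#' @param segment_labels Include letter segment labels (for partitions of at
#'   most 26 segments) mirroring the classic table layout.
#' @param L Chromosome length recorded as a `# L=` header comment (defaults
#'   to the table's `"L"` attribute).
#' @return `path`, invisibly.
#' @export
write_breakpoints <- function(bp, path, segment_labels = FALSE,
                              L = attr(bp, "L")) {
  stopifnot(inherits(bp, "sv_breakpoints"))
  out <- as.data.frame(bp)
  if (segment_labels && !is.null(L)) {
    part <- partition_from_breakpoints(bp, L)
    if (part$n <= 26L) {
      seg_of <- function(pos, term)
        code_segment(label_code(pos, term, part))
      out$segment_low <- letters[seg_of(bp$pos_low, bp$terminus_low)]
      out$segment_high <- letters[seg_of(bp$pos_high, bp$terminus_high)]
      out <- out[, c("pos_low", "segment_low", "terminus_low",
                     "pos_high", "segment_high", "terminus_high")]
    }
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header_comments(L = L), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write breakpoints as BEDPE
#'
#' BEDPE has no native notion of a segment terminus, so the strand columns
#' carry it under a fixed convention: a `head` terminus (junction keeps the
#' reference bases to the *right* of the position) maps to strand `-`, a
#' `tail` terminus (keeps the bases to the left) to `+`.  Each mate is the
#' zero-based, half-open single-base interval ending at the breakpoint
#' position.  The conversion is lossless and round-trips.
#'
#' @param bp An [breakpoints()] table.
#' @param path File path.
#' @param chrom Chromosome name for both mates.
#' @param L Optional chromosome length attribute for the reader.
#' @return `write_bedpe`: `path` invisibly; `read_bedpe`: an
#'   [breakpoints()] table.
#' @export
write_bedpe <- function(bp, path, chrom = "chr1") {
  stopifnot(inherits(bp, "sv_breakpoints"))
  df <- data.frame(
    chrom1 = chrom, start1 = bp$pos_low - 1, end1 = bp$pos_low,
    chrom2 = chrom, start2 = bp$pos_high - 1, end2 = bp$pos_high,
    name = sprintf("bp%d", seq_len(nrow(bp))), score = ".",
    strand1 = ifelse(bp$terminus_low == "head", "-", "+"),
    strand2 = ifelse(bp$terminus_high == "head", "-", "+"))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_bedpe
#' @export
read_bedpe <- function(path, L = NULL) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(df) < 10L) stop("BEDPE needs at least 10 columns")
  bp <- breakpoints(df[[3]], ifelse(df[[9]] == "-", "head", "tail"),
                    df[[6]], ifelse(df[[10]] == "-", "head", "tail"))
  attr(bp, "L") <- L
  bp
}

#' Write a copy-number profile as a segment (SEG-like) table
#'
#' One row per collapsed constant-copy-number block, in reference
#' coordinates: columns `start`, `end`, `copy_number`.
#'
#' @param profile An `sv_profile`.
#' @param path Output path.
#' @param collapse Write collapsed blocks (default) or one row per segment.
#' @return `path`, invisibly.
#' @export
write_profile_seg <- function(profile, path, collapse = TRUE) {
  stopifnot(inherits(profile, "sv_profile"))
  df <- if (collapse) {
    cp <- collapse_profile(profile)
    data.frame(start = cp$start, end = cp$end, copy_number = cp$value)
  } else {
    pos <- profile$partition$pos
    data.frame(start = pos[-length(pos)], end = pos[-1],
               copy_number = profile$counts)
  }
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header_comments(L = profile$partition$L), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write and read scenarios as JSON lines
#'
#' The first line is a metadata object carrying the chromosome length and
#' partition boundaries (so the scenario is replayable on its own); each
#' further line is one event:
#' `{"order": i, "kind": ..., "span": [from, to], "phase": ...,
#'   "created_breakpoints": [...], "byproducts": [...]}`.
#'
#' @param scenario An [build_scenario()] result.
#' @param path File path.
#' @return `write_scenario_jsonl`: `path` invisibly;
#'   `read_scenario_jsonl`: an `sv_scenario` (events and partition; the
#'   annotations are restored verbatim).
#' @export
write_scenario_jsonl <- function(scenario, path) {
  stopifnot(inherits(scenario, "sv_scenario"))
  con <- file(path, "w"); on.exit(close(con))
  meta <- list(type = "shattersim_scenario", version = pkg_version(),
               L = scenario$partition$L,
               boundaries = scenario$partition$boundaries)
  writeLines(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA), con)
  for (i in seq_along(scenario$events)) {
    ev <- scenario$events[[i]]
    rec <- list(order = i, kind = ev$kind,
                span = c(ev$from, ev$to),
                phase = ev$phase %||% NA,
                created_breakpoints = ev$creates %||% character(),
                byproducts = ev$byproducts %||% character())
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA,
                                null = "null"), con)
  }
  invisible(path)
}

#' @rdname write_scenario_jsonl
#' @export
read_scenario_jsonl <- function(path) {
  lines <- readLines(path)
  stopifnot(length(lines) >= 1L)
  meta <- jsonlite::fromJSON(lines[1])
  if (!identical(meta$type, "shattersim_scenario"))
    stop("not a scenario file: ", path)
  partition <- segment_partition(meta$L, unlist(meta$boundaries))
  events <- lapply(lines[-1], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    ev <- rearrangement_event(rec$kind, rec$span[1], rec$span[2])
    ev$phase <- rec$phase
    ev$creates <- unlist(rec$created_breakpoints) %||% character()
    ev$byproducts <- unlist(rec$byproducts) %||% character()
    ev
  })
  structure(list(events = events, partition = partition,
                 observed = breakpoints(numeric(), character(),
                                        numeric(), character()),
                 chain = NULL, deleted_segments = integer(),
                 inversion_lower_bound = NA_integer_),
            class = "sv_scenario")
}

#' Write sweep or trajectory snapshots as TSV
#'
#' Header comments record the tool version, the resolved configuration and
#' the seed, so every run is reproducible from its output.
#'
#' @param x An `sv_sweep` or `sv_trajectory`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshots <- function(x, path) {
  if (inherits(x, "sv_sweep")) {
    snaps <- x$snapshots
    cfg <- x$config
  } else if (inherits(x, "sv_trajectory")) {
    snaps <- x$snapshots
    cfg <- x$config
  } else stop("`x` must be an sv_sweep or sv_trajectory")
  con <- file(path, "w"); on.exit(close(con))
  writeLines(header_comments(
    counting_mode = cfg$counting_mode, state_mode = cfg$state_mode,
    relaxed_fraction = cfg$relaxed_fraction,
    type_weights = unname(cfg$type_weights),
    realization_strategy = cfg$realization_strategy,
    seed = cfg$seed), con)
  utils::write.table(snaps, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshots
#' @export
read_snapshots <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
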