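#' Read a RepeatMasker-style TE table
#'
#' The interchange format is an 8-column TSV with header
#' `chrom, start, end, name, milli_div, strand, family, te_class`
#' (0-based half-open coordinates; `milli_div` is the instance's divergence
#' from its family consensus in substitutions per kb).
#'
#' @param path TSV path
#' @return a data.table of validated TE instances
#' @export
read_te_table <- function(path) {
  .assert(file.exists(path), "TE table not found: %s", path)
  dt <- data.table::fread(path, colClasses = list(character = "chrom"))
  need <- c("chrom", "start", "end", "name", "milli_div", "strand",
            "family", "te_class")
  .assert(all(need %in% names(dt)),
          "TE table must have columns %s", paste(need, collapse = ", "))
  bad <- which(!(dt$start >= 0 & dt$start < dt$end))
  .assert(!length(bad), "TE table %s: invalid coordinates at line(s) %s",
          path, paste(head(bad + 1L, 5), collapse = ", "))
  bad_cls <- which(!dt$te_class %in% .te_classes)
  .assert(!length(bad_cls),
          "TE table %s: unknown te_class at line(s) %s",
          path, paste(head(bad_cls + 1L, 5), collapse = ", "))
  bad_md <- which(!(dt$milli_div >= 0 & dt$milli_div <= 1000))
  .assert(!length(bad_md), "TE table %s: milli_div outside [0,1000] at line(s) %s",
          path, paste(head(bad_md + 1L, 5), collapse = ", "))
  dt
}

#' Write a TE table
#'
#' @param te data.table of TE instances (extra columns such as `te_id` are
#'   dropped)
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_te_table <- function(te, path) {
  cols <- c("chrom", "start", "end", "name", "milli_div", "strand",
            "family", "te_class")
  data.table::fwrite(te[, cols, with = FALSE], path, sep = "\t")
  invisible(path)
}

.te_gr <- function(te) gi(te$chrom, te$start, te$end)
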