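# Batch prediction over many structure files with per-chain summaries and
# the majority-class chain call.

#' Summarise a per-residue prediction for one chain
#'
#' Counts, percentages (denominator: modelled residues) and maximal runs of
#' predicted residue indices per solenoid class, plus the majority-class
#' chain call.
#'
#' @param pred A [predict_chain()] result.
#' @param pdb_id Identifier recorded in the output.
#' @return An object of class `chain_scan_record`.
#' @export
summarize_chain <- function(pred, pdb_id = "") {
  pr <- pred$per_residue
  n <- nrow(pr)
  per_class <- lapply(1:3, function(c) {
    sel <- pr$class == c
    runs <- rle(sel)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    on <- which(runs$values)
    ranges <- if (length(on))
      sprintf("%d-%d", pr$resno[starts[on]], pr$resno[ends[on]])
    else character(0)
    list(count = sum(sel), percentage = 100 * sum(sel) / n, ranges = ranges)
  })
  names(per_class) <- class_names()[2:4]
  rec <- structure(list(pdb_id = pdb_id, chain_id = pred$chain_id,
                        n_residues = n, per_class = per_class,
                        chain_call = NA_character_),
                   class = "chain_scan_record")
  rec$chain_call <- classify_chain(rec)
  rec
}

#' Majority-class chain call
#'
#' A chain is called a member of a solenoid class if 50% or more of its
#' residues are predicted to belong to that class; otherwise "none". At an
#' exact 50/50 split between two classes the lower class index wins.
#'
#' @param rec A [summarize_chain()] record.
#' @return The class integer (1..3) or `"none"`.
#' @export
classify_chain <- function(rec) {
  pc <- unname(vapply(rec$per_class, function(x) x$percentage, 1.0))
  if (max(pc) >= 50) which.max(pc) else "none"
}

#' @export
print.chain_scan_record <- function(x, ...) {
  cat(sprintf("<chain_scan_record> %s chain %s: %d residues, call %s\n",
              x$pdb_id, x$chain_id, x$n_residues,
              if (is.character(x$chain_call)) x$chain_call
              else class_names()[as.integer(x$chain_call) + 1L]))
  for (nm in names(x$per_class)) {
    pc <- x$per_class[[nm]]
    if (pc$count > 0)
      cat(sprintf("  %s: %d (%.2f%%) at %s\n", nm, pc$count, pc$percentage,
                  paste(pc$ranges, collapse = ",")))
  }
  invisible(x)
}

record_row <- function(rec) {
  row <- data.frame(pdb_id = rec$pdb_id, chain_id = rec$chain_id,
                    n_residues = rec$n_residues,
                    chain_call = as.character(rec$chain_call))
  for (c in 1:3) {
    pc <- rec$per_class[[c]]
    row[[paste0("count_", c)]] <- pc$count
    row[[paste0("pct_", c)]] <- pc$percentage
    row[[paste0("ranges_", c)]] <- paste(pc$ranges, collapse = ",")
  }
  row
}

#' Scan a set of structure files
#'
#' Runs [predict_chain()] on every chain of every file and summarises each.
#' Unreadable files or chains are logged and skipped, never fatal. Results
#' are optionally streamed to a TSV as they are produced.
#'
#' @param paths Character vector of structure file paths.
#' @param model A fitted [solenoid_net()].
#' @param chains Optional chain selector: `"all"` (default) or a character
#'   vector of chain IDs to restrict to where present.
#' @param out Optional TSV path streamed to as records complete.
#' @param failures_log Optional path for a failures log.
#' @param blocklist Optional character vector of pdb_ids to skip.
#' @return A data frame of scan records (one row per chain) with a
#'   `failures` attribute.
#' @export
scan_corpus <- function(paths, model, chains = "all", out = NULL,
                        failures_log = NULL, blocklist = character(0)) {
  rows <- list()
  failures <- character(0)
  wrote_header <- FALSE
  for (path in paths) {
    pdb_id <- sub("\\.(pdb|cif|mmcif|ent)$", "", basename(path),
                  ignore.case = TRUE)
    if (pdb_id %in% blocklist) next
    chain_ids <- tryCatch({
      ext <- tolower(tools::file_ext(path))
      s <- suppressWarnings(
        if (ext %in% c("cif", "mmcif")) bio3d::read.cif(path, verbose = FALSE)
        else bio3d::read.pdb(path, verbose = FALSE))
      unique(s$atom$chain[s$atom$elety == "CA"])
    }, error = function(e) {
      failures <<- c(failures, paste0(path, "\t", conditionMessage(e)))
      NULL
    })
    if (is.null(chain_ids)) next
    if (!length(chain_ids)) {
      failures <- c(failures, paste0(path, "\tno C-alpha atoms parsed"))
      next
    }
    if (!identical(chains, "all")) chain_ids <- intersect(chain_ids, chains)
    for (ch in chain_ids) {
      rec <- tryCatch(
        summarize_chain(predict_chain(path, ch, model), pdb_id),
        error = function(e) {
          failures <<- c(failures,
                         paste0(path, ":", ch, "\t", conditionMessage(e)))
          NULL
        })
      if (is.null(rec)) next
      row <- record_row(rec)
      rows[[paste(pdb_id, ch)]] <- row
      if (!is.null(out)) {
        utils::write.table(row, out, sep = "\t", quote = FALSE,
                           row.names = FALSE, col.names = !wrote_header,
                           append = wrote_header)
        wrote_header <- TRUE
      }
    }
  }
  if (!is.null(failures_log) && length(failures))
    writeLines(failures, failures_log)
  result <- if (length(rows)) do.call(rbind, rows) else data.frame()
  rownames(result) <- NULL
  attr(result, "failures") <- failures
  result
}
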