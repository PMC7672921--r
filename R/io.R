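#' Read and write designs as bit-exact CSV schedules
#'
#' The design file format has header `cluster,crossover_slot,s1,...,sM`, one
#' row per cluster, with `crossover_slot` in `1..M+1` and the `s` columns
#' holding 0/1 recruitment indicators. The condition (control or
#' intervention) of each recruited slot is deliberately *not* stored: it is
#' recomputed from `crossover_slot`, so a file can never encode an
#' inconsistent schedule. Writing then reading a design returns an
#' identical object.
#'
#' @param path file path.
#' @param design an [sw_design()].
#' @return `read_design()` returns an [sw_design()]; `write_design()`
#'   returns `path` invisibly.
#' @export
read_design <- function(path) {
  sw_check(file.exists(path), sprintf("design file not found: %s", path))
  dat <- tryCatch(
    read.csv(path, check.names = FALSE, colClasses = "numeric"),
    error = function(e)
      sw_stop(sprintf("cannot parse design file %s: %s", path,
                      conditionMessage(e)), "swhunt_parse"),
    warning = function(w)
      sw_stop(sprintf("cannot parse design file %s: %s", path,
                      conditionMessage(w)), "swhunt_parse"))
  M <- ncol(dat) - 2L
  if (M < 1 || !identical(names(dat),
                          c("cluster", "crossover_slot", paste0("s", seq_len(M)))))
    sw_stop("malformed design file header: expected cluster,crossover_slot,s1,...,sM",
            "swhunt_parse")
  K <- nrow(dat)
  if (K < 1) sw_stop("design file has no cluster rows", "swhunt_parse")
  if (!identical(as.numeric(dat$cluster), as.numeric(seq_len(K))))
    sw_stop("cluster column must be 1..K in order", "swhunt_parse")
  cr <- dat$crossover_slot
  bad <- which(!is.finite(cr) | cr != as.integer(cr) | cr < 1 | cr > M + 1)
  if (length(bad))
    sw_stop(sprintf("crossover_slot out of range 1..M+1 at row %d", bad[1]),
            "swhunt_parse")
  rec <- as.matrix(dat[, paste0("s", seq_len(M)), drop = FALSE])
  badc <- which(matrix(!(rec %in% c(0, 1)), nrow(rec)), arr.ind = TRUE)
  if (nrow(badc))
    sw_stop(sprintf("non-binary recruitment cell at row %d, column s%d",
                    badc[1, 1], badc[1, 2]), "swhunt_parse")
  sw_design(as.integer(cr), rec)
}

#' @rdname read_design
#' @export
write_design <- function(design, path) {
  assert_design(design)
  K <- length(design$crossover)
  M <- ncol(design$recruit)
  df <- data.frame(cluster = seq_len(K), crossover_slot = design$crossover)
  rec <- as.data.frame(design$recruit)
  names(rec) <- paste0("s", seq_len(M))
  write.csv(cbind(df, rec), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a search trajectory log as CSV
#'
#' Columns: `iteration`, `step_type` (`sweep`, `remove` or `add`), `n`,
#' `variance`, `precision`.
#'
#' @param trajectory an `sw_trajectory` from [forward_search()] or
#'   [backward_search()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(trajectory, path) {
  sw_check(inherits(trajectory, "sw_trajectory"),
           "trajectory must come from forward_search()/backward_search()")
  write.csv(trajectory$records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
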