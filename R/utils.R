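# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state, restoring the caller's state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    seed <- as.integer(seed)
    if (is.na(seed)) stop("seed must be coercible to integer")
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# Derive a per-stage seed from a master seed; stays within 32-bit integer range.
derive_seed <- function(master_seed, offset) {
  as.integer((as.double(master_seed) * 7919 + 104729 * offset) %% 2147483647)
}

# Write a data.frame as TSV with full double precision so matrices round-trip.
write_tsv_full <- function(df, path, row_label = NULL) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  if (!is.null(row_label)) {
    df <- cbind(stats::setNames(data.frame(rownames(df), stringsAsFactors = FALSE),
                                row_label), df)
    rownames(df) <- NULL
  }
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.17g", x))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) e)
  if (!isTRUE(ok)) stop("failed to write '", path, "': ", conditionMessage(ok))
  invisible(path)
}

read_tsv_matrix <- function(path, row_label) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!row_label %in% names(df)) {
    stop("'", path, "' lacks expected column '", row_label, "'")
  }
  rn <- df[[row_label]]
  df[[row_label]] <- NULL
  m <- as.matrix(df)
  rownames(m) <- rn
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

match_two_groups <- function(groups, case_level = NULL) {
  groups <- as.character(groups)
  lv <- sort(unique(groups))
  if (length(lv) != 2L) {
    stop("expected exactly 2 groups, got ", length(lv))
  }
  if (is.null(case_level)) {
    case_level <- if ("MDD" %in% lv) "MDD" else lv[[1L]]
  }
  if (!case_level %in% lv) stop("case level '", case_level, "' not found in groups")
  list(case = case_level, control = setdiff(lv, case_level),
       is_case = groups == case_level)
}
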