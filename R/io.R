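#' Write conformations as an extended XYZ trajectory
#'
#' One frame per snapshot; the comment line carries `step`, the energy
#' decomposition and the box edge when present.
#'
#' @param frames A [conformation()] or list of them.
#' @param path Output file.
#' @param spec Optional [model_spec()]; when given, energies are computed
#'   and written on the comment line.
#' @param steps Optional per-frame step labels.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(frames, path, spec = NULL, steps = NULL) {
  if (inherits(frames, "polymer_conf")) frames <- list(frames)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(frames)) {
    cf <- frames[[i]]
    step <- if (is.null(steps)) i else steps[i]
    cmt <- paste0("step=", step,
                  " chains=", cf$n_chains)
    if (!is.null(spec)) {
      e <- total_energy(cf, spec)
      cmt <- paste0(cmt, sprintf(" Ep=%.10g ELJ=%.10g EBend=%.10g",
                                 e$ep, e$elj, e$ebend))
    }
    if (!is.null(cf$box)) cmt <- paste0(cmt, sprintf(" L=%.10g", cf$box))
    writeLines(as.character(nrow(cf$positions)), con)
    writeLines(cmt, con)
    writeLines(sprintf("C %.12g %.12g %.12g", cf$positions[, 1],
                       cf$positions[, 2], cf$positions[, 3]), con)
  }
  invisible(path)
}

#' Read an extended XYZ trajectory
#'
#' Tolerates a missing box entry (single-chain runs); the `chains=` field
#' of the comment line restores the chain map.
#'
#' @param path File written by [write_xyz()] (or any plain XYZ; one chain
#'   is assumed when `chains=` is absent).
#' @return A list of [conformation()] objects.
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  out <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    cmt <- lines[i + 1]
    getf <- function(key) {
      m <- regmatches(cmt, regexec(paste0(key, "=([-0-9.eE+]+)"), cmt))[[1]]
      if (length(m) == 2) as.numeric(m[2]) else NULL
    }
    chains <- getf("chains") %||% 1
    boxL <- getf("L")
    fields <- do.call(rbind, strsplit(trimws(lines[(i + 2):(i + 1 + n)]),
                                      "\\s+"))
    pos <- matrix(as.numeric(fields[, 2:4]), ncol = 3)
    out[[length(out) + 1]] <- conformation(pos, chains, boxL)
    i <- i + 2 + n
  }
  out
}

#' Write a weight table (or histogram) as TSV
#'
#' Columns `bin_left`, `bin_right`, `lnw` and, when available, `count`.
#' Round-trips bit-exactly through [read_weight_table()] (values printed
#' at full double precision).
#'
#' @param weights A [weight_table()].
#' @param path Output file.
#' @param hist Optional per-bin counts to store alongside.
#' @return `path`, invisibly.
#' @export
write_weight_table <- function(weights, path, hist = NULL) {
  df <- as.data.frame(tidy(weights)[, c("bin_left", "bin_right", "lnw")])
  if (!is.null(hist)) df$count <- hist
  out <- vapply(df, function(col) sprintf("%.17g", col),
                character(nrow(df)))
  utils::write.table(rbind(colnames(df), out), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_weight_table
#' @export
read_weight_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  de <- df$bin_right[1] - df$bin_left[1]
  w <- weight_table(df$bin_left[1], de, df$lnw)
  if (!is.null(df$count)) w$meta$hist <- df$count
  w
}
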