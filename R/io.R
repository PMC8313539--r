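#' Read a trial CSV
#'
#' Reads the canonical per-trial interchange format: comma-separated UTF-8
#' with header columns `subject`, `speed_cond`, `contrast_cond`, `correct`,
#' `rt_s` (RT in seconds), and an optional `origin` column
#' (`guess`/`diffusion`) carried by synthetic data.  Validation failures
#' name the offending data rows.
#'
#' @param path file path.
#' @return A trial data.frame with columns `subject`, `speed_cond`,
#'   `contrast_cond`, `correct`, `rt` (and `origin` when present).
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "speed_cond", "contrast_cond", "correct", "rt_s")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  bad_rows <- function(bad, what) {
    if (any(bad))
      stop(sprintf("%s in row(s): %s", what,
                   paste(utils::head(which(bad), 10L), collapse = ", ")),
           call. = FALSE)
  }
  bad_rows(!df$speed_cond %in% 1:5, "speed_cond outside 1-5")
  bad_rows(!df$contrast_cond %in% 1:5, "contrast_cond outside 1-5")
  bad_rows(!df$correct %in% 0:1, "correct not 0/1")
  bad_rows(!is.finite(df$rt_s) | df$rt_s <= 0, "nonpositive rt_s")
  out <- data.frame(subject = df$subject, speed_cond = as.integer(df$speed_cond),
                    contrast_cond = as.integer(df$contrast_cond),
                    correct = as.integer(df$correct), rt = df$rt_s)
  if ("origin" %in% names(df)) out$origin <- df$origin
  out
}

#' Write a trial CSV
#'
#' Writes trials in the canonical interchange format.  RTs are serialized
#' with 17 significant digits, so a write/read round trip reproduces every
#' value exactly.
#'
#' @param trials trial data.frame (as produced by [simulate_dataset()] or
#'   [read_trials()]).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  if (!"subject" %in% names(trials))
    stop("trials must have a 'subject' column", call. = FALSE)
  out <- data.frame(subject = trials$subject,
                    speed_cond = trials$speed_cond,
                    contrast_cond = trials$contrast_cond,
                    correct = trials$correct,
                    rt_s = sprintf("%.17g", trials$rt))
  if ("origin" %in% names(trials)) out$origin <- trials$origin
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write and read design parameter tables
#'
#' Serializes a [design_params()] object as a tidy CSV (`parameter`,
#' `index`, `value`) mirroring the conventional layout of published
#' parameter tables for the 5 x 5 design.
#'
#' @param design a [design_params()] object.
#' @param path file path.
#' @return `write_design()` returns `path` invisibly; `read_design()`
#'   returns a [design_params()] object.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "design_params"))
  rows <- rbind(
    data.frame(parameter = "a", index = 1:5, value = design$a),
    data.frame(parameter = "ter", index = 1:5, value = design$ter),
    data.frame(parameter = "p_o", index = 1:5, value = design$p_o),
    data.frame(parameter = "v", index = 1:5, value = design$v),
    data.frame(parameter = c("eta", "sz", "st", "mu_g", "s_g", "s"),
               index = NA_integer_,
               value = c(design$eta, design$sz, design$st, design$mu_g,
                         design$s_g, design$s)))
  rows$value <- sprintf("%.17g", rows$value)
  write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("parameter", "index", "value")
  if (!all(need %in% names(df)))
    stop("design file must have columns parameter, index, value",
         call. = FALSE)
  vec <- function(nm) {
    sub <- df[df$parameter == nm, ]
    sub$value[order(sub$index)]
  }
  scal <- function(nm) df$value[df$parameter == nm][1]
  design_params(a = vec("a"), ter = vec("ter"), p_o = vec("p_o"),
                v = vec("v"), eta = scal("eta"), sz = scal("sz"),
                st = scal("st"), mu_g = scal("mu_g"), s_g = scal("s_g"),
                s = if ("s" %in% df$parameter) scal("s") else ddm_noise_scale())
}

# key=value config files for the command-line interface; values are parsed
# as logical, numeric (comma-separated for vectors), or character.
read_config_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L)
      stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    parsed <- if (tolower(val) %in% c("true", "false")) {
      as.logical(val)
    } else {
      num <- suppressWarnings(as.numeric(strsplit(val, ",")[[1]]))
      if (!anyNA(num)) num else val
    }
    out[[key]] <- parsed
  }
  out
}
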