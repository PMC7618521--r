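# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) stop("need >= 2 columns to compute row variances")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

.geomean <- function(x) exp(mean(log(x)))

# md5 of a canonical text serialization; used for config hashes and manifests
.hash_object <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f), add = TRUE)
  con <- file(f, open = "wb")
  writeLines(deparse(x, control = c("keepNA", "keepInteger", "showAttributes")),
             con, sep = "\n")
  close(con)
  unname(tools::md5sum(f))
}

# Derive a named substream seed from the run seed so that adding a stage does
# not perturb another stage's draws. Stays below 2^31 - 1.
.stage_seed <- function(seed, stage) {
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((as.numeric(seed) %% 2147483647 * 31 + h * 2654435) %% 2147483647)
}

.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
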