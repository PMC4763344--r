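# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so package functions never perturb the
# session RNG stream. `seed = NULL` leaves the stream untouched.
local_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# Derive a stream of child seeds (< 2^31) from one parent seed.
child_seeds <- function(seed, n) {
  local_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

cv_log <- function(..., verbose = getOption("crossview.verbose", FALSE)) {
  if (isTRUE(verbose)) message("[crossview] ", ...)
  invisible(NULL)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

stop_cv <- function(..., class = "crossview_error") {
  rlang::abort(paste0(...), class = class)
}

assert_that <- function(ok, ...) {
  if (!isTRUE(ok)) stop_cv(...)
  invisible(TRUE)
}

DIAGNOSIS_LEVELS <- c("NC", "MCI", "AD")

VIEW_NAMES <- c("GMV", "LGI", "CNV", "SLD", "M-IDX", "F-IDX",
                "DoG-M", "DoG-C", "DoG-Z")

MRI_VIEWS <- c("GMV", "LGI", "CNV", "SLD")
PET_VIEWS <- c("M-IDX", "F-IDX", "DoG-M", "DoG-C", "DoG-Z")

ROI_CATEGORIES <- c("cortical", "ventricle", "central-structure",
                    "cerebellum", "brainstem", "other-noncortical")
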