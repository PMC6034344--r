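# Mixed-integer solver backend.
#
# The backend contract is minimal: binaries, continuous variables, linear
# two-sided constraints, a linear objective and a time limit in; status,
# variable values and objective out. The bundled backend is the HiGHS
# branch-and-bound solver driven through SciPy's milp() in a short Python
# helper, called once per batch of models so solver start-up cost is paid
# once. Models are exchanged as JSON (+/-Inf encoded as nulls).

backend_script <- function() {
  p <- system.file("python", "milp_solve.py", package = "indexsel")
  if (p == "") stop("solver error: bundled backend script not found")
  p
}

python_binary <- function() {
  p <- getOption("indexsel.python", Sys.getenv("INDEXSEL_PYTHON", "python"))
  full <- Sys.which(p)
  if (full == "") stop("solver error: python interpreter '", p, "' not found on PATH")
  full
}

# models: list of lists with nvar, obj, integrality, lb, ub,
#         con_i/con_j/con_v (1-based triplets), con_lb, con_ub.
# Returns a list (one element per model) with fields
#   status ("optimal" | "feasible_time_limited" | "infeasible" | "error"),
#   objective, x, message.
milp_backend <- function(models, options = solver_options()) {
  enc <- function(v) ifelse(is.finite(v), v, NA_real_)  # NA -> null -> inf
  payload <- list(
    time_limit = options$time_limit,
    models = lapply(models, function(m) list(
      nvar = m$nvar, obj = m$obj, integrality = m$integrality,
      lb = enc(m$lb), ub = enc(m$ub),
      con_i = m$con_i - 1L, con_j = m$con_j - 1L, con_v = m$con_v,
      con_lb = enc(m$con_lb), con_ub = enc(m$con_ub))))
  infile <- tempfile(fileext = ".json")
  outfile <- tempfile(fileext = ".json")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  jsonlite::write_json(payload, infile, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  status <- system2(python_binary(), c(backend_script(), infile, outfile),
                    stdout = TRUE, stderr = TRUE)
  code <- attr(status, "status")
  if (!is.null(code) && code != 0) {
    stop("solver error: backend exited with code ", code, "\n",
         paste(status, collapse = "\n"))
  }
  out <- jsonlite::read_json(outfile, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  lapply(out, function(r) list(status = r$status,
                               objective = if (is.null(r$objective)) NA_real_ else r$objective,
                               x = if (is.null(r$x)) NULL else unlist(r$x),
                               message = if (is.null(r$message)) "" else r$message))
}

#' Is the mixed-integer solver backend available?
#'
#' Checks that a Python interpreter with SciPy's `milp` can be launched.
#'
#' @return Logical scalar.
#' @export
solver_available <- function() {
  ok <- tryCatch({
    out <- system2(python_binary(),
                   c("-c", shQuote("from scipy.optimize import milp")),
                   stdout = TRUE, stderr = TRUE)
    is.null(attr(out, "status")) || attr(out, "status") == 0
  }, error = function(e) FALSE)
  isTRUE(ok)
}
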