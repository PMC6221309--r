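param_cols <- c("Sa_um", "Sal_um", "Spc_inv_um", "Smr1_pct")
param_names <- c("Sa", "Sal", "Spc", "Smr1")

# Deterministic column order of the full-interaction (M3) fixed design.
m3_column_names <- function() {
  c("(Intercept)", "locLR", "locDP", "mold", "rescan", "logTime",
    "manGS", "manSF", "manGS:logTime", "manSF:logTime",
    "matFS:logTime", "matPL:logTime",
    "manGS:matFS:logTime", "manGS:matPL:logTime",
    "manSF:matFS:logTime", "manSF:matPL:logTime")
}

#' Log-transform the observation table
#'
#' Builds the response matrix `Y = ln(Sa, Sal, Spc, Smr1)` (n x 4, natural
#' logs) and the covariate `logTime = ln(time + 1)`, so that rows with
#' time 0 have `logTime = 0` and form the baseline against which change
#' over time is measured.
#'
#' @param records Observation `data.frame` with columns `Sa_um`, `Sal_um`,
#'   `Spc_inv_um`, `Smr1_pct` and `time_min`.
#' @return A list with `Y` (n x 4 matrix, columns Sa, Sal, Spc, Smr1),
#'   `logTime`, and the input `records`.
#' @export
log_transform_table <- function(records) {
  raw <- as.matrix(records[, param_cols])
  bad <- which(!is.finite(raw) | raw <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive texture parameter in row %d (%s)",
                 bad[1, 1], param_cols[bad[1, 2]]))
  if (any(records$time_min < 0)) stop("negative time in observation table")
  Y <- log(raw)
  colnames(Y) <- param_names
  list(Y = Y, logTime = log(records$time_min + 1), records = records)
}

# Group the five scan locations into the three modelled categories:
# Center, Left+Right, Distal+Proximal.
group_location <- function(location) {
  out <- ifelse(location %in% c("L", "R"), "LR",
                ifelse(location %in% c("D", "P"), "DP",
                       ifelse(location == "C", "C", NA)))
  if (anyNA(out))
    stop("unknown scan location: ", paste(unique(location[is.na(out)]),
                                          collapse = ", "))
  factor(out, levels = c("C", "LR", "DP"))
}

#' Fixed-effect design matrix for the model ladder M0-M3
#'
#' Dummy coding with baselines: location C, bone (not mold), not rescanned,
#' manufacturing state UW, material DB. Material enters only through
#' interactions with `logTime`, so at time 0 all material terms vanish and
#' the manufacturing states alone separate the samples.
#'
#' * `M0`: intercept only (random-effects-only model).
#' * `M1`: + location (2), bone-vs-mold (1), rescan (1), logTime (1).
#' * `M2`: + manufacture (2), manufacture:logTime (2), material:logTime (2).
#' * `M3`: + manufacture:material:logTime (4) — 16 columns in total.
#'
#' @param table Observation `data.frame` with columns `location`,
#'   `is_mold`, `is_rescan`, `time_min`, `state`, `material`.
#' @param model_id One of `"M0"`, `"M1"`, `"M2"`, `"M3"`.
#' @return Numeric design matrix with deterministic column names.
#' @export
build_fixed_design <- function(table, model_id = "M3") {
  model_id <- match.arg(model_id, c("M0", "M1", "M2", "M3"))
  n <- nrow(table)
  X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  if (model_id == "M0") return(X)

  loc <- group_location(table$location)
  state <- table$state
  if (!all(state %in% c("UW", "GS", "SF")))
    stop("unknown manufacturing state level")
  mat <- table$material
  if (!all(mat %in% c("FS", "PL", "DB")))
    stop("unknown material level")
  logTime <- log(table$time_min + 1)

  X <- cbind(X,
             locLR = as.numeric(loc == "LR"),
             locDP = as.numeric(loc == "DP"),
             mold = as.numeric(table$is_mold),
             rescan = as.numeric(table$is_rescan),
             logTime = logTime)
  if (model_id == "M1") return(X)

  manGS <- as.numeric(state == "GS")
  manSF <- as.numeric(state == "SF")
  matFS <- as.numeric(mat == "FS")
  matPL <- as.numeric(mat == "PL")
  X <- cbind(X, manGS = manGS, manSF = manSF,
             "manGS:logTime" = manGS * logTime,
             "manSF:logTime" = manSF * logTime,
             "matFS:logTime" = matFS * logTime,
             "matPL:logTime" = matPL * logTime)
  if (model_id == "M2") return(X)

  X <- cbind(X,
             "manGS:matFS:logTime" = manGS * matFS * logTime,
             "manGS:matPL:logTime" = manGS * matPL * logTime,
             "manSF:matFS:logTime" = manSF * matFS * logTime,
             "manSF:matPL:logTime" = manSF * matPL * logTime)
  X
}

# Specimen and lot indices (1-based) for each row, plus level tables.
random_effect_indices <- function(table) {
  spec_levels <- sort(unique(table$specimen))
  lot_of <- tapply(table$lot, table$specimen, function(x) {
    u <- unique(x)
    if (length(u) != 1L) stop("specimen assigned to multiple lots")
    u
  })
  if (anyNA(lot_of)) stop("orphan specimen without a lot")
  lot_levels <- sort(unique(table$lot))
  list(spec_idx = match(table$specimen, spec_levels),
       lot_idx = match(table$lot, lot_levels),
       spec_levels = spec_levels, lot_levels = lot_levels,
       n_spec = length(spec_levels), n_lot = length(lot_levels))
}

#' Random-effects design matrix
#'
#' Zero/one incidence matrix with one column per specimen followed by one
#' column per lot; each row carries exactly one 1 in the specimen block and
#' one 1 in the lot block. For the default registry this is an n x 42
#' matrix (37 specimens + 5 lots).
#'
#' @param table Observation `data.frame` with `specimen` and `lot` columns.
#' @return Numeric matrix `Z` with named columns.
#' @export
build_random_design <- function(table) {
  zi <- random_effect_indices(table)
  n <- nrow(table)
  Z <- matrix(0, n, zi$n_spec + zi$n_lot,
              dimnames = list(NULL, c(zi$spec_levels, zi$lot_levels)))
  Z[cbind(seq_len(n), zi$spec_idx)] <- 1
  Z[cbind(seq_len(n), zi$n_spec + zi$lot_idx)] <- 1
  attr(Z, "indices") <- zi
  Z
}
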