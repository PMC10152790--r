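#' Per-payer cost vector
#'
#' A cost split across the three payer categories of the model: third-party
#' payers (TPP: private insurance, NSSF, civil servants' cooperative, army,
#' ISF, MoPH), out-of-pocket household payments (OOP), and central-bank drug
#' subsidies (BDL). All amounts are in thousand LBP, the canonical internal
#' currency unit; conversion to USD happens only at reporting time.
#'
#' @param tpp,oop,bdl Non-negative finite amounts in thousand LBP.
#' @return A named numeric vector of class `payer_costs` with components
#'   `tpp`, `oop`, `bdl`.
#' @examples
#' payer_costs(tpp = 80, oop = 20)
#' payer_costs(444, 467, 5250) + payer_costs(314, 471, 2800)
#' @export
payer_costs <- function(tpp = 0, oop = 0, bdl = 0) {
  x <- c(tpp = as.numeric(tpp), oop = as.numeric(oop), bdl = as.numeric(bdl))
  if (any(!is.finite(x)) || any(x < 0)) {
    stop("payer cost components must be non-negative and finite", call. = FALSE)
  }
  structure(x, class = "payer_costs")
}

#' @export
print.payer_costs <- function(x, ...) {
  cat(sprintf("<payer_costs> TPP %s | OOP %s | BDL %s | total %s (1,000 LBP)\n",
              format(x[["tpp"]], big.mark = ","),
              format(x[["oop"]], big.mark = ","),
              format(x[["bdl"]], big.mark = ","),
              format(total_cost(x), big.mark = ",")))
  invisible(x)
}

payer_names <- c("tpp", "oop", "bdl")

as_payer_costs <- function(x) {
  if (inherits(x, "payer_costs")) return(x)
  if (is.numeric(x) && length(x) == 3) {
    if (is.null(names(x))) names(x) <- payer_names
    return(payer_costs(x[["tpp"]], x[["oop"]], x[["bdl"]]))
  }
  stop("cannot coerce to payer_costs", call. = FALSE)
}

#' Total cost across payers
#'
#' @param x A `payer_costs` vector.
#' @return `tpp + oop + bdl`, thousand LBP.
#' @export
total_cost <- function(x) {
  x <- as_payer_costs(x)
  sum(unclass(x))
}

# arithmetic keeps the class; scaling and addition are the only operations the
# model needs (expected values are convex combinations of cost vectors)
#' @export
Ops.payer_costs <- function(e1, e2) {
  out <- NextMethod()
  if (.Generic %in% c("+", "-", "*", "/")) {
    out <- structure(as.numeric(out),
                     names = payer_names, class = "payer_costs")
  }
  out
}

zero_costs <- function() payer_costs(0, 0, 0)

#' Cost table constructor
#'
#' A procedure cost table: one row per medical procedure, with the cost split
#' across payers for both price epochs (pre- and post-collapse). Pre-collapse
#' BDL subsidies do not exist, so `pre_bdl` must be zero throughout.
#'
#' @param procedure_id Character vector of unique procedure identifiers.
#' @param label Human-readable procedure names.
#' @param pre_tpp,pre_oop Pre-collapse costs (thousand LBP).
#' @param post_tpp,post_oop,post_bdl Post-collapse costs (thousand LBP).
#' @return A data frame of class `cost_table`.
#' @export
cost_table <- function(procedure_id, label, pre_tpp, pre_oop,
                       post_tpp, post_oop, post_bdl) {
  stopifnot(!anyDuplicated(procedure_id))
  vals <- cbind(pre_tpp, pre_oop, post_tpp, post_oop, post_bdl)
  if (any(!is.finite(vals)) || any(vals < 0)) {
    stop("cost table entries must be non-negative and finite", call. = FALSE)
  }
  out <- data.frame(
    procedure_id = as.character(procedure_id),
    label = as.character(label),
    pre_tpp = as.numeric(pre_tpp), pre_oop = as.numeric(pre_oop),
    pre_bdl = 0,
    post_tpp = as.numeric(post_tpp), post_oop = as.numeric(post_oop),
    post_bdl = as.numeric(post_bdl),
    stringsAsFactors = FALSE
  )
  class(out) <- c("cost_table", "data.frame")
  out
}

#' Extract the per-payer cost matrix for one price epoch
#'
#' @param table A `cost_table`.
#' @param epoch `"pre"` or `"post"`.
#' @return A numeric matrix (procedures x payers) with rownames =
#'   procedure ids and colnames `tpp`, `oop`, `bdl`, thousand LBP.
#' @export
epoch_costs <- function(table, epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  cols <- paste0(epoch, "_", payer_names)
  m <- as.matrix(table[, cols])
  dimnames(m) <- list(table$procedure_id, payer_names)
  m
}

#' Look up one procedure's per-payer costs
#'
#' @param table A `cost_table`.
#' @param procedure_id One procedure id.
#' @param epoch `"pre"` or `"post"`.
#' @return A `payer_costs` vector.
#' @export
procedure_costs <- function(table, procedure_id, epoch = c("pre", "post")) {
  epoch <- match.arg(epoch)
  i <- match(procedure_id, table$procedure_id)
  if (is.na(i)) {
    stop(sprintf("unknown procedure id '%s'", procedure_id), call. = FALSE)
  }
  payer_costs(table[[paste0(epoch, "_tpp")]][i],
              table[[paste0(epoch, "_oop")]][i],
              table[[paste0(epoch, "_bdl")]][i])
}
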