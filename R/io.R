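#' Read a genes-by-samples expression matrix from TSV
#'
#' Expected layout: a header row whose first field names the identifier
#' column (conventionally `gene_id`) followed by sample identifiers; each
#' subsequent row is a gene identifier followed by one numeric value per
#' sample. Identifiers are preserved in file order.
#'
#' @param path path to a tab-separated file.
#' @return numeric matrix with gene rownames and sample colnames.
#' @seealso [writeExpression()], [normalizeExpression()]
#' @export
readExpression <- function(path) {
    lines <- readLines(path)
    if (length(lines) < 2)
        stop("expression file must contain a header and at least one gene")
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    if (any(nf != nf[1]))
        stop("ragged row ", which(nf != nf[1])[1], " in ", path,
             ": expected ", nf[1], " fields, found ",
             nf[which(nf != nf[1])[1]])
    sampleIds <- parts[[1]][-1]
    if (anyDuplicated(sampleIds))
        stop("duplicated sample identifier: ",
             sampleIds[duplicated(sampleIds)][1])
    body <- parts[-1]
    geneIds <- vapply(body, `[[`, character(1), 1)
    if (anyDuplicated(geneIds))
        stop("duplicated gene identifier: ", geneIds[duplicated(geneIds)][1])
    vals <- suppressWarnings(
        as.numeric(unlist(lapply(body, `[`, -1), use.names = FALSE)))
    if (anyNA(vals)) {
        bad <- ceiling(which(is.na(vals))[1] / length(sampleIds))
        stop("non-numeric cell in data row ", bad, " (gene ",
             geneIds[bad], ")")
    }
    matrix(vals, nrow = length(geneIds), byrow = TRUE,
           dimnames = list(geneIds, sampleIds))
}

#' Write an expression matrix as TSV
#'
#' Canonical format: `gene_id` header column, one row per gene, numbers
#' written with full precision (`format(..., digits = 15)` trimmed).
#'
#' @param x numeric matrix with gene rownames and sample colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeExpression <- function(x, path) {
    stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
    header <- paste(c("gene_id", colnames(x)), collapse = "\t")
    body <- vapply(seq_len(nrow(x)), function(i) {
        paste(c(rownames(x)[i],
                formatC(x[i, ], format = "g", digits = 15)),
              collapse = "\t")
    }, character(1))
    writeLines(c(header, body), path)
    invisible(path)
}

#' Read / write a sample annotation table
#'
#' The annotation TSV carries one row per sample with (at minimum) columns
#' `sample_id` and `tp53_status`; the full clinical layout also includes
#' `disease_stage`, `os_days`, `os_event`, `blast_pct`, `wbc`, `eln2022`
#' and `allelic`.
#'
#' @param path path to a tab-separated file.
#' @return `data.frame` with one row per sample.
#' @export
readAnnotation <- function(path) {
    ann <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    if (!"sample_id" %in% colnames(ann))
        stop("annotation file must contain a 'sample_id' column")
    if (anyDuplicated(ann$sample_id))
        stop("duplicated sample_id: ",
             ann$sample_id[duplicated(ann$sample_id)][1])
    ann
}

#' @rdname readAnnotation
#' @param ann annotation `data.frame`.
#' @export
writeAnnotation <- function(ann, path) {
    utils::write.table(ann, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read / write a drugs-by-samples AUC matrix
#'
#' Same TSV layout as the expression matrix, with drug identifiers in the
#' first column. Missing values are allowed (`NA`).
#'
#' @param path path to a tab-separated file.
#' @param stage stage tag for the returned object.
#' @return A [DrugResponse-class] object.
#' @export
readDrugResponse <- function(path, stage = "raw_auc") {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                             check.names = FALSE)
    ids <- tab[[1]]
    if (anyDuplicated(ids))
        stop("duplicated drug identifier: ", ids[duplicated(ids)][1])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- ids
    DrugResponse(m, stage = stage)
}

#' @rdname readDrugResponse
#' @param x A `DrugResponse`.
#' @export
writeDrugResponse <- function(x, path) {
    stopifnot(is(x, "DrugResponse"))
    m <- aucValues(x)
    tab <- data.frame(drug_id = rownames(m), m, check.names = FALSE)
    utils::write.table(tab, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one set per line, tab-separated set name, description,
#' then gene identifiers.
#'
#' @param path path to a `.gmt` file.
#' @return named list of character vectors of gene identifiers.
#' @export
readGeneSets <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < 3)
    if (length(bad))
        stop("GMT line ", bad[1], " has fewer than 3 fields")
    sets <- lapply(parts, function(p) unique(p[-(1:2)]))
    names(sets) <- vapply(parts, `[[`, character(1), 1)
    if (anyDuplicated(names(sets)))
        stop("duplicated gene-set name: ",
             names(sets)[duplicated(names(sets))][1])
    sets
}

#' Read a plain one-gene-per-line list (e.g. surface-marker genes)
#'
#' @param path text file with one gene identifier per line; blank lines
#'   and leading/trailing whitespace are ignored.
#' @return character vector of unique gene identifiers in file order.
#' @export
readGeneList <- function(path) {
    x <- trimws(readLines(path))
    unique(x[nzchar(x)])
}

#' Serialize / load a penalized logistic model as JSON
#'
#' The JSON carries `gene_ids`, `beta`, `beta0`, `lambda`, `alpha` and
#' `input_stage` at full numeric precision, so reloaded models reproduce
#' ridge scores bit-exactly.
#'
#' @param model A [PenalizedModel-class].
#' @param path output / input path.
#' @return `writePenalizedModel`: `path`, invisibly.
#'   `readPenalizedModel`: a `PenalizedModel`.
#' @export
writePenalizedModel <- function(model, path) {
    stopifnot(is(model, "PenalizedModel"))
    jsonlite::write_json(
        list(gene_ids = model@geneIds, beta = model@beta,
             beta0 = model@beta0, lambda = model@lambda,
             alpha = model@alpha, input_stage = model@inputStage),
        path, auto_unbox = TRUE, digits = I(17))
    invisible(path)
}

#' @rdname writePenalizedModel
#' @export
readPenalizedModel <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    new("PenalizedModel", geneIds = as.character(obj$gene_ids),
        beta = as.numeric(obj$beta), beta0 = as.numeric(obj$beta0),
        lambda = as.numeric(obj$lambda), alpha = as.numeric(obj$alpha),
        inputStage = as.character(obj$input_stage))
}
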