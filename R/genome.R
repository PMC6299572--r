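#' Default chromosome-arm definitions (hg19-like)
#'
#' Returns a table of chromosome arms for the 22 autosomes plus X and Y,
#' with arm boundaries derived from the hg19 centromere gaps. Coordinates
#' are 1-based inclusive. The acrocentric chromosomes (13, 14, 15, 21, 22)
#' carry no usable p arm: their short arms consist of rDNA/satellite
#' material not covered by array markers, so only the q arm is listed and
#' flagged acrocentric.
#'
#' The exact base-pair boundaries are a bundled fixture for simulation and
#' arm-fraction arithmetic, not a genomic claim.
#'
#' @return A data.frame with columns `chromosome` (character), `arm`
#'   ("p" or "q"), `start_bp`, `end_bp` (1-based inclusive) and
#'   `acrocentric` (logical).
#' @examples
#' arms <- make_default_genome()
#' subset(arms, chromosome == "13")  # q only
#' @export
make_default_genome <- function() {
  # chromosome length and centromere gap (hg19, UCSC gap table)
  chrom <- c(as.character(1:22), "X", "Y")
  len <- c(249250621, 243199373, 198022430, 191154276, 180915260,
           171115067, 159138663, 146364022, 141213431, 135534747,
           135006516, 133851895, 115169878, 107349540, 102531392,
           90354753, 81195210, 78077248, 59128983, 63025520,
           48129895, 51304566, 155270560, 59373566)
  cen_start <- c(121535434, 92326171, 90504854, 49660117, 46405641,
                 58830166, 58054331, 43838887, 47367679, 39254935,
                 51644205, 34856694, 16000000, 16000000, 17000000,
                 35335801, 22263006, 15460898, 24681782, 26369569,
                 11288129, 13000000, 58632012, 10104553)
  cen_end <- c(124535434, 95326171, 93504854, 52660117, 49405641,
               61830166, 61054331, 46838887, 50367679, 42254935,
               54644205, 37856694, 19000000, 19000000, 20000000,
               38335801, 25263006, 18460898, 27681782, 29369569,
               14288129, 16000000, 61632012, 13104553)
  acro <- c("13", "14", "15", "21", "22")

  rows <- lapply(seq_along(chrom), function(i) {
    ch <- chrom[i]
    q <- data.frame(chromosome = ch, arm = "q",
                    start_bp = cen_end[i] + 1, end_bp = len[i],
                    acrocentric = ch %in% acro,
                    stringsAsFactors = FALSE)
    if (ch %in% acro) return(q)
    p <- data.frame(chromosome = ch, arm = "p",
                    start_bp = 1, end_bp = cen_start[i] - 1,
                    acrocentric = FALSE, stringsAsFactors = FALSE)
    rbind(p, q)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Length of an arm in base pairs
#' @param arms arm-definition table
#' @param chromosome,arm arm to look up
#' @return integer length, or NA if the arm is not defined
#' @keywords internal
arm_length <- function(arms, chromosome, arm) {
  i <- which(arms$chromosome == chromosome & arms$arm == arm)
  if (length(i) == 0L) return(NA_real_)
  arms$end_bp[i] - arms$start_bp[i] + 1
}

#' Assign markers to chromosome arms
#'
#' Markers falling inside a defined arm get that arm label; markers in the
#' centromeric gap (or on an undefined arm, e.g. acrocentric p) are flagged
#' `NA` and are excluded from run detection downstream.
#'
#' @param chromosome,position marker coordinates (vectors)
#' @param arms arm-definition table from [make_default_genome()]
#' @return character vector of arm labels ("p"/"q"/NA)
#' @export
assign_arms <- function(chromosome, position, arms) {
  out <- rep(NA_character_, length(chromosome))
  for (i in seq_len(nrow(arms))) {
    hit <- chromosome == arms$chromosome[i] &
      position >= arms$start_bp[i] & position <= arms$end_bp[i]
    out[hit] <- arms$arm[i]
  }
  out
}

#' Validate an arm-definition table
#' @param arms candidate table
#' @return the table, invisibly; stops on violation
#' @keywords internal
validate_arms <- function(arms) {
  stopifnot(all(c("chromosome", "arm", "start_bp", "end_bp",
                  "acrocentric") %in% names(arms)))
  if (any(arms$start_bp >= arms$end_bp))
    stop("arm definitions must satisfy start_bp < end_bp")
  for (ch in unique(arms$chromosome)) {
    sub <- arms[arms$chromosome == ch, ]
    if (all(c("p", "q") %in% sub$arm)) {
      if (sub$end_bp[sub$arm == "p"] > sub$start_bp[sub$arm == "q"])
        stop("p arm must precede q arm on chromosome ", ch)
    }
  }
  invisible(arms)
}
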