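#include <Rcpp.h>
#include <string>
#include <cctype>
using namespace Rcpp;

// Parse one samtools-mpileup base string + quality string into filtered,
// reference-strand base counts (A,C,G,T,N plus '*' deletions counted as N).
//
// Markers handled: '^' starts a read and is followed by one mapping-quality
// character (both consumed, no quality attached); '$' ends a read; '+n.../-n...'
// inline indel blocks are skipped and consume no quality; '.'/',' are the
// reference base on the forward/reverse read strand; letters are alternative
// bases, lowercase meaning reverse-strand reads (case folded: counts are
// reference-strand base counts); '>'/'<' reference skips are ignored; '*' is
// a deletion placeholder. Every '.', ',', letter, '>', '<' and '*' consumes
// one quality character (Phred+33); calls with Phred < min_phred are dropped.

// [[Rcpp::export(name = ".parse_pileup_bases")]]
IntegerVector parse_pileup_bases(std::string bases, std::string quals,
                                 char ref, int min_phred) {
  int nA = 0, nC = 0, nG = 0, nT = 0, nN = 0;
  size_t qi = 0;
  const size_t nq = quals.size();
  ref = std::toupper((unsigned char)ref);
  size_t i = 0;
  while (i < bases.size()) {
    char c = bases[i];
    if (c == '^') {
      if (i + 1 >= bases.size()) stop("truncated '^' marker in pileup bases");
      i += 2; // caret + mapping quality char
      continue;
    }
    if (c == '$') { ++i; continue; }
    if (c == '+' || c == '-') {
      size_t j = i + 1, len = 0;
      if (j >= bases.size() || !std::isdigit((unsigned char)bases[j]))
        stop("malformed indel length in pileup bases");
      while (j < bases.size() && std::isdigit((unsigned char)bases[j])) {
        len = len * 10 + (bases[j] - '0');
        ++j;
      }
      if (j + len > bases.size()) stop("malformed indel length in pileup bases");
      i = j + len;
      continue;
    }
    // everything else consumes one quality char
    if (qi >= nq) stop("base and quality strings disagree in length");
    int phred = (int)quals[qi] - 33;
    ++qi;
    ++i;
    if (c == '>' || c == '<') continue; // reference skip: ignored entirely
    if (phred < min_phred) continue;
    char b;
    if (c == '.' || c == ',') b = ref;
    else if (c == '*') b = 'N'; // deletion: excluded from A/G arithmetic
    else b = std::toupper((unsigned char)c);
    switch (b) {
      case 'A': ++nA; break;
      case 'C': ++nC; break;
      case 'G': ++nG; break;
      case 'T': ++nT; break;
      default: ++nN; break;
    }
  }
  if (qi != nq) stop("base and quality strings disagree in length");
  IntegerVector out = IntegerVector::create(
      _["A"] = nA, _["C"] = nC, _["G"] = nG, _["T"] = nT, _["N"] = nN);
  return out;
}
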