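#ifndef POOLSCREEN_BASES_H
#define POOLSCREEN_BASES_H

#include <cstdint>
#include <string>
#include <vector>

// A=0 C=1 G=2 T=3, anything else (incl. N) = 4
inline uint8_t base_code(char c) {
    switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default:            return 4;
    }
}

inline char code_base(uint8_t b) {
    static const char tab[5] = {'A', 'C', 'G', 'T', 'N'};
    return tab[b];
}

inline char comp_base(char c) {
    switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'a': return 't'; case 'c': return 'g';
    case 'g': return 'c'; case 't': return 'a';
    default:  return 'N';
    }
}

inline std::string revcomp(const std::string &s) {
    std::string out(s.size(), 'N');
    for (size_t i = 0; i < s.size(); ++i)
        out[s.size() - 1 - i] = comp_base(s[i]);
    return out;
}

#endif
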