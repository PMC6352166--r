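replicon	start	end	in_reference	in_HB27A	in_HB27E
chromosome	259293	259789	NO	YES	YES
chromosome	386772	389127	NO	YES	YES
chromosome	562354	562716	NO	YES	YES
chromosome	1082351	1082693	NO	NO	YES
chromosome	1133885	1134345	NO	YES	YES
chromosome	1370579	1371607	YES	YES	YES
chromosome	1533343	1534271	YES	YES	YES
chromosome	1550847	1551323	NO	YES	YES
chromosome	1655564	1655957	NO	YES	YES
megaplasmid	23402	23834	NO	NO	YES
megaplasmid	57597	58625	YES	YES	YES
megaplasmid	72589	73617	YES	YES	YES
megaplasmid	85677	86705	YES	YES	YES
megaplasmid	154975	155865	NO	YES	YES
megaplasmid	159958	160986	YES	YES	YES
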