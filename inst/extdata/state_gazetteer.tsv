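# US state gazetteer: alias<TAB>canonical. Full names match case-insensitively;
# two-letter USPS abbreviations match as exact-case standalone tokens.
AL	Alabama
Alabama	Alabama
AK	Alaska
Alaska	Alaska
Arizona	Arizona
AZ	Arizona
AR	Arkansas
Arkansas	Arkansas
CA	California
California	California
CO	Colorado
Colorado	Colorado
Connecticut	Connecticut
CT	Connecticut
DE	Delaware
Delaware	Delaware
FL	Florida
Florida	Florida
GA	Georgia
Georgia	Georgia
Hawaii	Hawaii
HI	Hawaii
ID	Idaho
Idaho	Idaho
IL	Illinois
Illinois	Illinois
IN	Indiana
Indiana	Indiana
IA	Iowa
Iowa	Iowa
Kansas	Kansas
KS	Kansas
Kentucky	Kentucky
KY	Kentucky
LA	Louisiana
Louisiana	Louisiana
Maine	Maine
ME	Maine
Maryland	Maryland
MD	Maryland
MA	Massachusetts
Massachusetts	Massachusetts
MI	Michigan
Michigan	Michigan
Minnesota	Minnesota
MN	Minnesota
Mississippi	Mississippi
MS	Mississippi
Missouri	Missouri
MO	Missouri
Montana	Montana
MT	Montana
NE	Nebraska
Nebraska	Nebraska
Nevada	Nevada
NV	Nevada
New Hampshire	New Hampshire
NH	New Hampshire
New Jersey	New Jersey
NJ	New Jersey
New Mexico	New Mexico
NM	New Mexico
New York	New York
NY	New York
NC	North Carolina
North Carolina	North Carolina
ND	North Dakota
North Dakota	North Dakota
OH	Ohio
Ohio	Ohio
OK	Oklahoma
Oklahoma	Oklahoma
OR	Oregon
Oregon	Oregon
PA	Pennsylvania
Pennsylvania	Pennsylvania
Rhode Island	Rhode Island
RI	Rhode Island
SC	South Carolina
South Carolina	South Carolina
SD	South Dakota
South Dakota	South Dakota
Tennessee	Tennessee
TN	Tennessee
Texas	Texas
TX	Texas
UT	Utah
Utah	Utah
Vermont	Vermont
VT	Vermont
VA	Virginia
Virginia	Virginia
WA	Washington
Washington	Washington
West Virginia	West Virginia
WV	West Virginia
WI	Wisconsin
Wisconsin	Wisconsin
WY	Wyoming
Wyoming	Wyoming
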